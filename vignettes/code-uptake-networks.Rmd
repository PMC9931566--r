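---
title: "Characterizing a new diagnosis code: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a new diagnosis code: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lcnet` characterizes the early clinical use of a newly released
diagnosis code (ICD-10-CM U09.9, the long COVID code released in
October 2021) in tabular EHR extracts. This vignette is the package's
account of its methods: the models and rules implemented, the
parameters that matter, what the bundled synthetic-data generator does
and does not emulate, and the numerical conventions adopted where a
choice had to be made.

## Cohort model

The unit of analysis is a patient anchored at an **index date**: the
earliest occurrence of the index code inside the closed calendar window
2021-10-01 to 2022-05-26. Codes dated before the window start never
define an index. The code did not exist before its release date, so any
earlier occurrence is a retroactive annotation (for example a
problem-list onset date) whose timing cannot be trusted.

Two exclusions follow: deceased patients, and patients whose index date
falls inside (closed interval) an inpatient stay — during a
hospitalization, features co-occurring with the code cannot be
separated from the admission's primary cause. Sites contribute only if
they pass data-quality gates: at least 25% of inpatients with core labs
recorded, at least 75% of inpatient visits with valid end dates, dates
shifted by at most 30 days, and nonzero use of the index code.
Coverage thresholds are inclusive (exactly 0.25 and 0.75 pass; a
31-day shift fails).

All downstream analyses collect events in the **analysis window**, the
closed interval from index to index + 60 days. Two conventions are
fixed here and verified by tests:

* *The window endpoint is inclusive.* Whether day 60 belongs to the
  window is not externally determined; we use closed intervals for
  every date comparison in the package unless stated otherwise, and
  document each operation's boundary behavior.
* *Prior events never exclude a condition.* A condition recorded both
  before index and in-window is retained: pre-existing conditions can
  be exacerbated by, or newly co-occur with, the indexed disease.
  Clusters therefore represent co-occurrence, not causation.

Age groups are `<21`, `21-45`, `46-65`, `66+`, computed as completed
years at the index date with bins `[0,21)`, `[21,46)`, `[46,66)`,
`[66,Inf)`. Percentages in summaries are rounded half-up to one
decimal; an undefined percentage (zero denominator) is reported as
missing, never as 0.

## Co-occurrence networks and community detection

The network is built over the K = 30 conditions carried by the most
distinct patients in-window (the index code itself is never a
candidate; ties break lexicographically so the ranking is invariant to
row order). The weight of edge (i, j) is the number of distinct
patients whose window contains both i and j; weights are therefore
bounded by the smaller of the two per-condition patient counts, and
zero-weight pairs are dropped (they carry no modularity contribution).
Condition identity is the SNOMED-style display name from the bundled
crosswalk, so duplicate source codes mapping to one name collapse
before counting.

Quality of a partition is the weighted Newman–Girvan modularity

$$Q = \frac{1}{2m}\sum_{ij}\Big[A_{ij} - \gamma\frac{k_ik_j}{2m}\Big]\,\delta(c_i,c_j)$$

with weighted degrees $k$, total weight $m$, and resolution $\gamma$
(default 1, exposed as a parameter; larger values favour more, smaller
communities). At $\gamma = 1$ the single-community partition scores
exactly 0.

Three detection algorithms are implemented in the package (an external
graph library is used only as an independent cross-check in the test
suite):

* **Louvain** — two repeated phases: greedy local moves (each node
  joins the neighbouring community with the largest positive modularity
  gain) until no move helps, then aggregation of communities into
  supernodes. Node visitation order is shuffled by a seed, making runs
  deterministic; gain ties go to the lowest community index. The
  output's Q is never below the all-singleton start.
* **Girvan–Newman** — divisive removal of the edge with maximum
  shortest-path betweenness, with weights entering as distances
  $1/w$ (heavier co-occurrence = shorter path, the standard convention
  for similarity weights). Each removal's component partition is scored
  on the *original* graph, and the best along the dendrogram is
  returned. Betweenness ties break on the first edge in (row, column)
  order.
* **Walktrap** — agglomeration on t-step random-walk distances
  (t = 4, the algorithm's original default): each community's signature
  is the member-averaged t-step transition-probability vector,
  communities at squared distance
  $r^2_{CD} = \sum_k (P_{Ck}-P_{Dk})^2/d_k$ are merged (adjacent pairs
  only, smallest Ward-style cost first), and the merge tree is cut at
  maximum modularity. Zero-degree nodes stay as their own singleton
  communities.

On every small benchmark graph in the test suite, Louvain's Q is
checked against exhaustive enumeration of all partitions (203 for the
6-node two-triangle graph); the suite includes only graphs where the
greedy optimum is the global one, which the oracle verifies rather
than assumes. A practical note surfaced by the analysis scripts:
divisive betweenness performs poorly on dense, nearly complete
weighted graphs like the full top-30 network (its best dendrogram cut
peels off single nodes), which is consistent with preferring Louvain
as the headline model; Walktrap and Louvain agree on the planted
structure.

**Stability.** The stability analysis resamples patients with
replacement B times, rebuilds the network over the same node set,
re-runs detection, and records the adjusted Rand index (ARI) against
the full-data reference partition. The patient bootstrap + ARI design
is this package's instantiation of a network-stability check; other
designs (edge perturbation, node jackknife) exist, and the report
carries all replicate values so users can summarize differently.

**Age stratification** repeats the full pipeline (top-K, network,
detection) independently per age group, so the node sets may differ by
stratum; strata with fewer than two conditions are skipped with a
warning.

## Disparity statistics and disclosure control

Area-level SDoH variables (ACS-style percentages keyed by ZIP) are
categorized **high/medium/low** at percentile cutpoints of the *full*
ZIP reference table — not just cohort ZIPs — so the cohort's mix is
interpretable against the area distribution. The default cutpoints are
tertiles with linear-interpolation quantiles; the percentile pair is a
parameter, since the exact convention behind any published cutpoints
is rarely stated. Boundary rule: low strictly below the lower
cutpoint, high strictly above the upper, medium in the closed interval
between (a degenerate distribution labels everything medium).
Unmatched or missing ZIPs label as `missing`. Labels are invariant to
positive rescaling of the variable.

Group comparisons use the **G-test of independence**,
$G = 2\sum O\ln(O/E)$, zero cells contributing 0 (the
$x\ln x \to 0$ limit), no continuity or Williams correction, and
$p$ from the chi-square upper tail with $(r-1)(c-1)$ df. G is exactly
linear in counts at fixed proportions and approaches Pearson's
$X^2$ in the large-count, moderate-association regime (the test suite
checks 2% agreement with every cell ≥ 100 and multiplicative
deviations from independence within 5%). Post hoc per-category
comparisons are 2×2 G-tests Bonferroni-adjusted across the categories
of a variable. Tests always run on raw counts; disclosure-shifted
counts are display-only.

**Disclosure control.** Displayed tables suppress any count in
[1, 20) as `<20` (a count of exactly 20 is shown). Because a
suppressed cell is derivable from a displayed column margin, one
displayed complement cell per variable × age-group column — the
smallest, deterministically — is shifted by a seeded draw from
{±1..±5}, constrained so the shifted display stays at or above the
threshold, and, when exactly one cell is suppressed, so the candidate
set an attacker could derive for it (bounded to [1, 19]) never
collapses to a single value. Percentages are computed from the shifted
counts so the displayed table is internally consistent. Shifts are
drawn once per table build under the policy seed and are identical on
re-runs. Known corner: a column whose every cell is suppressed has no
displayable complement to shift; only the margin is then visible, and
degenerate margins (e.g. k suppressed cells summing to exactly k)
would still be informative. Such columns do not occur at the cohort
sizes the package targets.

## Practice-pattern summaries

Procedure analysis first removes encounter-only codes (E&M visit codes
that record that a visit happened, shipped as an editable fixture),
then aggregates to high-level categories (bundled fixture, ~13
categories) counting unique patients per category per stratum; the
display rule suppresses categories with fewer than 20 patients *or*
less than 1.0% of the stratum.

Medication analysis keeps, per patient, ingredients with at least one
record in-window and none at any time before index (full lookback), so
the result reflects newly started drugs; identity is at ingredient
level, the stable unit across products and doses. Classes are ATC
level 3, the 4-character prefix (letter, two digits, letter) of the
7-character code — e.g. `J01CA04` → `J01C`.

The uptake series counts unique patients per calendar month per
tracked code over the full lookback (not the cohort window), so the
handoff from the placeholder code B94.8 to U09.9 around the release
date is visible. Unique patients per month, rather than raw events, is
a fixed design choice (the alternative is configurable by grouping the
raw events differently); months are contiguous and zero-filled.

## The synthetic-data generator

Real enclave data are access-restricted, so the package ships a
generator whose outputs have *known ground truth*; its defaults are the
study conditions used throughout the tests and scripts.

Each patient draws an age group (default weights are the published
cohort proportions 2316 : 11364 : 13850 : 6252), then a latent symptom
subtype from the age group's mixture, then an index date uniform over
the release window. Conditions are emitted independently in-window
with probability (subtype emission + background); the default profiles
plant five blocks — neurological, cardiopulmonary, gastrointestinal,
upper respiratory, comorbid — of 6–8 conditions each at emission 0.5
over a 41-condition vocabulary, with background rate 0.03. Conditional
independence given the subtype is deliberate: it is the simplest
emission model under which community detection provably recovers the
blocks, and the true dependence structure among long COVID symptoms is
unknown — the generator makes no claim about it.

Flagged subsets (inpatient-index 3098/36880, acute hospitalization
3266/33782 of the base population, severe 791/3266 of the
hospitalized, missing COVID index 12550/33782) are allocated by exact
count (`round(frac × n)` under a seeded shuffle) rather than i.i.d.
draws. This satisfies "fractions hold in expectation" while making the
published attrition worked example an exact computation. The deceased
fraction defaults to 0 because the initial population is defined as
non-deceased code carriers. A configurable fraction of patients also
carries a placeholder B94.8 event dated before the coding switch date
(default 2021-10-01), planting the uptake handoff.

ZIP codes are sampled with weight $\exp(-s\,z_{\text{poverty}})$,
where s is the `sdoh_skew` parameter (0 = uniform): positive skew
over-represents low-poverty areas, emulating differential uptake of a
new code by area deprivation. SDoH variables per ZIP are independent
normals clipped to [0, 100] with means/sds chosen as plausible
ACS-style percentages (poverty 11 ± 5, college 14 ± 6, public
insurance 18 ± 7, unemployment 4.4 ± 1.6).

One master seed drives named RNG sub-streams (persons, events, visits,
tests, sites, sdoh), so adding a table never perturbs earlier draws
and identical configs give byte-identical tables. Dates are emitted as
ISO-8601 strings; all window arithmetic happens downstream.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: realistic visit-level utilization,
within-subtype symptom correlation beyond the shared block, clinically
plausible code sequencing, site-level heterogeneity in uptake timing,
free-text symptoms, and measurement error in SDoH estimates. Tests on
generated data validate the *machinery* (counting, windowing,
detection, suppression), not epidemiological claims.

## Problem sizes and runtime choices

The analysis scripts simulate 20,000 patients (plus a 30,000-patient
comparator); the attrition worked example uses 36,880 patients with a
lean one-block emission profile, since attrition depends only on the
flags; planted-recovery checks use 3,000 patients across four subtypes
and 20 replicate 30-node block graphs; bootstrap stability uses
B = 50. These sizes give stable results (recovery ARIs at or near 1,
binomial checks within 3 standard errors) while keeping any single
stage in seconds.

## Known limitations

* Billing versus clinical diagnosis context is not distinguishable in
  harmonized extracts; both are combined.
* The G-test/chi-square agreement bound holds in the stated regime
  only; strongly associated tables diverge, as the statistics should.
* Girvan–Newman is a poor fit for dense weighted networks (see above);
  it is provided as a comparator, not the headline model.
* In the missing-COVID-index worked example, the conventionally quoted
  37.2% for 12,550 of 33,782 patients is not reproducible under any
  standard one-decimal rounding (100·12550/33782 = 37.1499…); the
  package reports 37.1 and does not adopt a double-rounding convention
  to match the quoted figure.
* The severity flag (ventilator/ECMO/vasopressors) is taken from the
  input tables; resolving it from raw concept codes is out of scope.
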