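ingredient,atc7
albuterol,R03AC02
fluticasone,R01AD08
montelukast,R03DC03
guaifenesin,R05CA03
benzonatate,R05DB01
prednisone,H02AB07
dexamethasone,H02AB02
amoxicillin,J01CA04
azithromycin,J01FA10
doxycycline,J01AA02
sertraline,N06AB06
fluoxetine,N06AB03
amitriptyline,N06AA09
melatonin,N05CH01
ondansetron,A04AA01
omeprazole,A02BC01
famotidine,A02BA03
loperamide,A07DA03
metoprolol,C07AB02
amlodipine,C08CA01
lisinopril,C09AA03
atorvastatin,C10AA05
ibuprofen,M01AE01
acetaminophen,N02BE01
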