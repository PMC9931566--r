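snomed_name,icd10cm
Fatigue,R53.83
Chronic fatigue syndrome,R53.82
Headache,R51.9
Dizziness,R42
Memory impairment,R41.3
Anxiety disorder,F41.9
Depressive disorder,F32.9
Insomnia,G47.00
Dyspnea,R06.02
Cough,R05.9
Chest pain,R07.9
Palpitations,R00.2
Tachycardia,R00.0
Hypoxemia,R09.02
Wheezing,R06.2
Asthma,J45.909
Abdominal pain,R10.9
Nausea,R11.0
Vomiting,R11.10
Diarrhea,R19.7
Gastroesophageal reflux disease,K21.9
Constipation,K59.00
Acute pharyngitis,J02.9
Acute upper respiratory infection,J06.9
Nasal congestion,R09.81
Sinusitis,J32.9
Anosmia,R43.0
Dysgeusia,R43.2
Essential hypertension,I10
Type 2 diabetes mellitus,E11.9
Hyperlipidemia,E78.5
Obesity,E66.9
Congestive heart failure,I50.9
Atrial fibrillation,I48.91
Coronary atherosclerosis,I25.10
Chronic obstructive pulmonary disease,J44.9
Fever,R50.9
Myalgia,M79.1
Arthralgia,M25.50
Sleep apnea,G47.33
Malaise,R53.81
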