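code,description
99202,Office or other outpatient visit new patient
99203,Office or other outpatient visit new patient
99204,Office or other outpatient visit new patient
99205,Office or other outpatient visit new patient
99211,Office or other outpatient visit established patient
99212,Office or other outpatient visit established patient
99213,Office or other outpatient visit established patient
99214,Office or other outpatient visit established patient
99215,Office or other outpatient visit established patient
99385,Preventive medicine visit
99395,Preventive medicine visit
99421,Online digital evaluation and management
99441,Telephone evaluation and management
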