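code,category
71046,radiography
71250,radiography
74018,radiography
70450,radiography
93000,electrocardiography
93010,electrocardiography
93306,echocardiography
93307,echocardiography
94010,pulmonary function testing
94060,pulmonary function testing
94729,pulmonary function testing
97110,physical therapy
97112,physical therapy
97116,physical therapy
97165,occupational therapy
97530,occupational therapy
80053,laboratory
85025,laboratory
84443,laboratory
94640,respiratory therapy
93224,cardiac monitoring
93784,cardiac monitoring
95810,sleep study
90834,behavioral health
90837,behavioral health
92507,speech therapy
96365,infusion
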