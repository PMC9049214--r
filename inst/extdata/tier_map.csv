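code_system,code_prefix,category,tier
ICD10,N39,urinary_tract_infection,1
ICD10,N30,urinary_tract_infection,1
ICD10,N10,urinary_tract_infection,1
ICD10,J13,pneumonia,1
ICD10,J14,pneumonia,1
ICD10,J15,pneumonia,1
ICD10,J16,pneumonia,1
ICD10,J18,pneumonia,1
ICD10,L02,skin_soft_tissue_infection,1
ICD10,L03,skin_soft_tissue_infection,1
ICD10,L08,skin_soft_tissue_infection,1
ICD10,A54,sexually_transmitted_infection,1
ICD10,A56,sexually_transmitted_infection,1
ICD10,A40,other_tier1_bacterial_infection,1
ICD10,A41,other_tier1_bacterial_infection,1
ICD10,A49,other_tier1_bacterial_infection,1
ICD10,G00,other_tier1_bacterial_infection,1
ICD10,I33,other_tier1_bacterial_infection,1
ICD10,M86,other_tier1_bacterial_infection,1
ICD10,H66,acute_otitis_media,2
ICD10,H67,acute_otitis_media,2
ICD10,J01,acute_sinusitis,2
ICD10,J02,acute_pharyngitis,2
ICD10,J03,acute_tonsillitis,2
ICD10,A02,infectious_gastroenteritis,2
ICD10,A03,infectious_gastroenteritis,2
ICD10,A04,infectious_gastroenteritis,2
ICD10,A05,infectious_gastroenteritis,2
ICD10,A09,infectious_gastroenteritis,2
ICD10,J44,chronic_obstructive_pulmonary_disease,2
ICD10,H60,otitis_externa,2
ICD10,L70,acne,2
ICD10,J32,chronic_sinusitis,2
ICD10,H10,eye_infection,2
ICD10,N70,pelvic_inflammatory_disease,2
ICD10,N71,pelvic_inflammatory_disease,2
ICD10,N72,pelvic_inflammatory_disease,2
ICD10,N73,pelvic_inflammatory_disease,2
ICD10,K04,dental_infection,2
ICD10,K05,dental_infection,2
ICD10,J05,other_respiratory_infection,2
ICD10,J36,other_respiratory_infection,2
ICD10,J39,other_respiratory_infection,2
ICD10,N34,other_tier2_diagnosis,2
ICD10,K61,other_tier2_diagnosis,2
ICD10,H70,other_tier2_diagnosis,2
ICD10,J20,acute_bronchitis,3
ICD10,J21,acute_bronchitis,3
ICD10,J00,viral_upper_respiratory_infection,3
ICD10,J06,viral_upper_respiratory_infection,3
ICD10,B34,viral_upper_respiratory_infection,3
ICD10,J09,influenza,3
ICD10,J10,influenza,3
ICD10,J11,influenza,3
ICD10,R50,unspecific_fever,3
ICD10,J45,asthma,3
ICD10,J30,allergy,3
ICD10,L50,allergy,3
ICD10,K52,non_infectious_gastroenteritis,3
ICD10,K29,gastritis,3
ICD10,I10,cardiovascular_disease,3
ICD10,I20,cardiovascular_disease,3
ICD10,I25,cardiovascular_disease,3
ICD10,E11,diabetes,3
ICD10,E14,diabetes,3
ICD10,R10,non_specific_digestive_symptoms,3
ICD10,R11,non_specific_digestive_symptoms,3
ICD10,K59,non_specific_digestive_symptoms,3
TCM,BNL,tcm,1
TCM,BNF,tcm,2
TCM,BWG,tcm,2
TCM,BNG,tcm,3
TCM,BNX,tcm,3
TCM,B,tcm,3
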