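"regional_health_name","health_district_name","health_care_facility_name","health_care_service_name","num_examination","code_icd10_or_icpc2","code_atc","code_loinc","examination_date","patient_sex","patient_age","patient_nationality","patient_habitation","local_concept_diagnosis","standard_concept_diagnosis","local_concept_medicine","standard_concept_medicine","local_concept_biology","standard_concept_biology"
"North","Upper North","Central Clinic","Outpatient","G1","B54",,,"2018-03-01","F","30","Gabonaise","Ntoum","paludisme","Paludisme",,,,
"North","Upper North","Central Clinic","Outpatient","G1",,"N02BE01",,"2018-03-01","F","30","Gabonaise","Ntoum",,,"Paracétamol","Paracétamol",,
"North","Upper North","Central Clinic","Outpatient","G2",,,,"2018-03-02","F","30","Gabonaise","Ntoum",,,,,,
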