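variable,category,cohort,reference
age_category,<1,2,4
age_category,1-4,182,170
age_category,5-9,374,301
age_category,10-14,434,402
age_category,15-19,403,600
gender,male,1058,1007
gender,female,337,470
race,white,951,1131
race,black,131,203
race,other,294,130
race,unknown,19,13
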