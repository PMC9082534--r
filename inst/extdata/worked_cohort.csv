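id,sex,age_band,length_of_incarceration,violent_index_offense,previous_violent_crime,civil_status,education,employment,income,alcohol_misuse,drug_misuse,any_mental_disorder,any_severe_mental_disorder,outcome,outcome_available
w01,male,a18_29,lt6m,0,0,other,lt9y,1,low,0,0,1,0,0,TRUE
w02,male,a30_39,lt6m,1,0,unmarried,y9_11,0,stable,1,0,0,0,1,TRUE
w03,female,a40_49,lt6m,0,1,other,ge12y,1,low,0,0,1,0,0,TRUE
w04,male,a50plus,m6_12,1,0,unmarried,lt9y,0,stable,0,1,0,1,1,TRUE
w05,male,a18_29,m6_12,0,0,other,y9_11,1,low,1,0,1,0,0,TRUE
w06,female,a30_39,m6_12,1,1,unmarried,ge12y,0,stable,0,0,0,0,1,TRUE
w07,male,a40_49,m12_24,0,0,other,lt9y,1,low,0,0,1,0,0,TRUE
w08,male,a50plus,m12_24,1,0,unmarried,y9_11,0,stable,1,1,0,1,1,TRUE
w09,female,a18_29,m12_24,0,1,other,ge12y,1,low,0,0,1,0,0,TRUE
w10,male,a30_39,ge24m,1,0,unmarried,lt9y,0,stable,0,0,0,0,1,TRUE
w11,male,a40_49,ge24m,0,0,other,y9_11,1,low,1,0,1,0,0,TRUE
w12,female,a50plus,ge24m,1,1,unmarried,ge12y,0,stable,0,1,0,1,1,TRUE
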