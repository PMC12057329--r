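column,type,range,description
patient_id,string,,Unique patient identifier
arm,string,CAT|CBT,Guided self-help arm received (CAT-GSH or CBT-GSH)
allocation,string,preference|randomized,Allocation route into the arm
sessions,integer,0-8,Number of attended sessions
age,numeric,,Age in years
female,integer,0|1,Female flag
white_british,integer,0|1,White-British ethnicity flag
imd_decile,integer,1-10,Index of multiple deprivation decile (1 poorest)
unemployed,integer,0|1,Unemployment flag
perinatal,integer,0|1,Perinatal-period flag
heterosexual,integer,0|1,Heterosexual orientation flag
previous_cat,integer,0|1,Previous cognitive analytic therapy flag
previous_cbt,integer,0|1,Previous cognitive behavioural therapy flag
previous_treatment,integer,0|1,Any previous psychological treatment flag
ltc,integer,0|1,Long-term condition flag
medication,integer,0|1,Psychotropic medication flag
phq9_baseline,integer,0-27,Baseline PHQ-9 depression score
wsas_baseline,integer,0-40,Baseline WSAS functional impairment score
bai_baseline,integer,0-63,Baseline Beck Anxiety Inventory score
gad7_baseline,integer,0-21,Baseline GAD-7 anxiety score (forced-entry covariate)
gad7_post,integer,0-21,Post-treatment (week 8) GAD-7 score (outcome)
gad7_followup,integer,0-21,Follow-up (week 24) GAD-7 score
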