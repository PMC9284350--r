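fixture,user_id,pregnancy_index,start,end,exposure_class,adverse_outcomes,ga_days,weight_oz,term_ga_evidence,normal_bw_evidence,indications
user1,user1,1,2019-07-29,2020-05-04,EXPLICIT_DURING,PRETERM;NICU;LOW_BIRTH_WEIGHT,248,76,FALSE,FALSE,
user2,user2,1,2019-09-16,2020-06-22,INFERRED_DURING,,269,117,TRUE,TRUE,cardiomyopathy
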