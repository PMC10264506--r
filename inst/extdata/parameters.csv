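name,family,mean,ci_low,ci_high,group,units,source
age_start,normal,64.1,46.9,80.7,,years,Longitudinal EC survivor cohort
p_cvd_14yr,beta,0.158,0.144,0.172,,probability,Longitudinal EC survivor cohort (14-year follow-up)
share_stroke,dirichlet,0.35,,,cvd_split,proportion,Longitudinal EC survivor cohort
share_chd,dirichlet,0.31,,,cvd_split,proportion,Longitudinal EC survivor cohort
share_hf,dirichlet,0.34,,,cvd_split,proportion,Longitudinal EC survivor cohort
p_fatal_stroke,lognormal,0.478,0.360,0.586,,probability,SMR of uterine cancer survivors dying of stroke within 12 months
p_fatal_chd_hf,lognormal,0.424,0.342,0.493,,probability,SMR of uterine cancer survivors dying of CHD/HF within 12 months
s5_post_chd,beta,0.859,0.832,0.885,,probability,Australian longitudinal study (5-year survival after CHD)
s5_post_stroke,beta,0.731,0.628,0.824,,probability,Australian longitudinal study (5-year survival after stroke)
s5_post_hf,beta,0.705,0.703,0.707,,probability,Australian longitudinal study (5-year survival after heart failure)
p_recurrence_14yr,beta,0.240,0.205,0.278,,probability,Longitudinal EC survivor cohort (14-year follow-up)
q_age,table,,,,,probability,Australian Life Table 2022 (age-specific female mortality)
s5_post_recurrence,beta,0.625,0.462,0.775,,probability,SEER regional-stage relative survival after recurrence
hr_cvd_exercise,lognormal,0.770,0.67,0.88,,ratio,Exercise trial in non-metastatic breast cancer survivors
hr_recurrence_exercise,lognormal,0.330,0.17,0.64,,ratio,Case-control study of endometrial cancer survivors
u_baseline,table,,,,,utility,Australian EQ-5D-3L study of EC survivors (age-specific)
du_recurrence,gamma,0.112,0.09985,0.1246,,disutility,Utility decrement in cancer recurrence
u_post_stroke,beta,0.651,0.474,0.810,,utility,Systematic review of general-population utilities
u_post_chd,beta,0.720,0.650,0.787,,utility,Systematic review of general-population utilities
u_post_hf,beta,0.789,0.727,0.846,,utility,Systematic review of general-population utilities
du_stroke,gamma,0.0750,0.0423,0.116,,disutility,One-time disutility of first-time stroke
du_chd,gamma,0.15,0.0843,0.230,,disutility,One-time disutility of first-time CHD
du_hf,gamma,0.07,0.0398,0.108,,disutility,One-time disutility of first-time heart failure
c_exercise,gamma,1381,377,3006,,AUD,ACUMEN trial / MBS No. 23 (18 supervised sessions)
c_surveillance,gamma,1601,40,5930,,AUD,MBS (physical examination and CT surveillance)
c_stroke_acute,gamma,12215,3293,26650,,AUD,Australian costing study (acute stroke treatment)
c_chd_acute,gamma,10177,2847,22383,,AUD,Australian costing study (acute CHD treatment)
c_hf_acute,gamma,10270,2830,22577,,AUD,Australian costing study (acute HF treatment)
c_post_stroke_fu,gamma,5662,1502,12353,,AUD,Australian costing study (post-stroke follow-up)
c_post_chd_fu,gamma,3348,951,7360,,AUD,Australian costing study (post-CHD follow-up)
c_post_hf_fu,gamma,4101,1086,9047,,AUD,Australian costing study (post-HF follow-up)
c_recurrence_treatment,gamma,13126,3558,28773,,AUD,MBS (EBRT with vaginal brachytherapy)
c_recurrence_fu,gamma,4880,1348,10642,,AUD,Follow-up cancer care after recurrence
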