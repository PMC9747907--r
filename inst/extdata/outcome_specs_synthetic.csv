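name,dimension,rr_outcome,p_outcome,iq_points_per_ptb,unit_cost,currency_year,include_in_total,countable
neonatal_death,health,5.0,0.003,NA,NA,2015,FALSE,TRUE
child_asthma,health,1.13,0.07,NA,0.023,2015,TRUE,TRUE
T1D,health,1.18,0.0003,NA,0.20,2014,TRUE,TRUE
T2D,health,1.68,0.10,NA,0.049,2014,TRUE,TRUE
reduced_IQ,cognition,NA,NA,8.4,0.0113,2015,TRUE,FALSE
ASD,non-cognition,2.0,0.007,NA,1.806,2015,TRUE,TRUE
ADHD,non-cognition,1.5,0.07,NA,0.182,2015,TRUE,TRUE
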