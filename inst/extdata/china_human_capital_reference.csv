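scenario,outcome,dimension,n_point,n_lo,n_hi,cost_musd,include_in_total
actual,aPTB,direct,13262,6962,18802,929.7,FALSE
actual,neonatal_death,health,178,93,253,NA,FALSE
actual,child_asthma,health,125,66,177,2.9,TRUE
actual,T1D,health,5,3,8,1.0,TRUE
actual,T2D,health,628,329,891,30.5,TRUE
actual,reduced_IQ,cognition,111400,58480,157936,1258.6,TRUE
actual,ASD,non-cognition,876,460,1243,1582.0,TRUE
actual,ADHD,non-cognition,453,238,643,82.5,TRUE
anthropogenic,aPTB,direct,4609,711,6111,323.1,FALSE
anthropogenic,neonatal_death,health,62,9,82,NA,FALSE
anthropogenic,child_asthma,health,43,7,58,1.0,TRUE
anthropogenic,T1D,health,2,0,3,0.4,TRUE
anthropogenic,T2D,health,218,34,290,10.6,TRUE
anthropogenic,reduced_IQ,cognition,38715,5972,51332,437.4,TRUE
anthropogenic,ASD,non-cognition,304,47,404,549.0,TRUE
anthropogenic,ADHD,non-cognition,157,24,209,28.6,TRUE
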