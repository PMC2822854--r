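ring,burrow,deployed,recovery,days,mass_deployment_g,mass_recovery_g,data_recovered
25459,144,2006-02-26,2006-03-02,4,900,850,TRUE
25659,101,2006-03-02,2006-03-04,2,700,660,TRUE
25421,75,2006-03-02,2006-03-03,1,855,785,TRUE
25507,140,2006-02-23,2006-03-06,11,600,660,TRUE
30854,7,2006-02-24,2006-03-08,12,680,NA,FALSE
31155,81,2006-02-26,tracker lost,NA,585,NA,FALSE
31103,8,2006-02-23,2006-03-01,6,700,740,TRUE
31272,7,2006-02-24,2006-03-01,5,850,770,TRUE
32005,68,2006-03-02,returned later,NA,665,NA,TRUE
33312,265,2006-02-24,tracker lost,NA,580,NA,FALSE
33715,316,2006-02-23,2006-02-25,2,660,795,TRUE
33757,244,2006-02-24,2006-02-28,4,660,790,TRUE
33759,257,2006-02-23,tracker lost,NA,610,NA,FALSE
34999,204,2006-02-24,tracker lost,NA,690,NA,FALSE
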