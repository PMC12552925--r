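stratum,strategy,cost,qaly,incr_cost,incr_qaly
base,CTBS,351000,6.55,NA,NA
base,PSMA_PET,451000,7.12,99000,0.58
base,CTBS_PLUS_PSMA,459000,7.03,8000,-0.09
lt2,CTBS,351000,7.43,NA,NA
lt2,PSMA_PET,412000,7.97,61000,0.54
lt2,CTBS_PLUS_PSMA,423000,7.84,12000,-0.13
2to5,CTBS,377000,6.00,NA,NA
2to5,PSMA_PET,514000,6.60,137000,0.60
2to5,CTBS_PLUS_PSMA,519000,6.55,5000,-0.05
ge5,CTBS,353000,5.40,NA,NA
ge5,PSMA_PET,495000,6.01,142000,0.62
ge5,CTBS_PLUS_PSMA,497000,5.99,2000,-0.03
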