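"name","stratum","family","mean","ui_low","ui_high","voi_group","units","source_note"
"p_detect_psma","base","beta",0.7512,0.7105,0.788,NA,"probability","published"
"p_detect_psma","lt2","beta",0.6019,0.5431,0.6652,2,"probability","published"
"p_detect_psma","2to5","beta",0.867,0.7807,0.9295,NA,"probability","published"
"p_detect_psma","ge5","beta",0.9369,0.8905,0.9714,NA,"probability","published"
"p_loc_given_detect","base","beta",0.1857,0.1477,0.2252,NA,"probability","published"
"p_loc_given_detect","lt2","beta",0.2545,0.1871,0.3224,2,"probability","published"
"p_loc_given_detect","2to5","beta",0.1404,0.0729,0.2296,NA,"probability","published"
"p_loc_given_detect","ge5","beta",0.1369,0.0852,0.196,NA,"probability","published"
"p_met_given_detect","base","beta",0.8146,0.7731,0.8538,NA,"probability","published"
"p_met_given_detect","lt2","beta",0.7449,0.6707,0.8088,NA,"probability","published"
"p_met_given_detect","2to5","beta",0.8606,0.7733,0.9299,NA,"probability","published"
"p_met_given_detect","ge5","beta",0.8632,0.8029,0.9187,NA,"probability","published"
"p_loc_given_ctbs_detect","base","beta",0.0342,0.0071,0.0832,1,"probability","published"
"p_met_after_local_nrd","base","beta",0.0227,0.0187,0.0271,2,"annual probability","published"
"hr_early","base","lognormal",0.56,0.49,0.92,1,"hazard ratio","published"
"hr_false_negative","base","lognormal",1.79,1.09,2.05,1,"hazard ratio","published"
"sens_ctbs","base","beta",0.3798,0.249,0.5285,1,"probability","published"
"spec_ctbs","base","beta",0.9101,0.8406,0.9601,1,"probability","published"
"cost_psma_pet","base","gamma",1898,1242,2727,3,"USD one-off","published"
"cost_ctbs","base","gamma",1327,851,1863,3,"USD one-off","published"
"cost_prostatectomy","base","gamma",12442,7828,18163,NA,"USD one-off","published"
"cost_radiation","base","gamma",17606,11473,25534,NA,"USD one-off","published"
"cost_cryotherapy","base","gamma",15845,9978,22035,NA,"USD one-off","published"
"cost_adt","base","gamma",4049,2548,5769,3,"USD per year","published"
"cost_arsi","base","gamma",88492,56523,126237,3,"USD per year","published"
"cost_mdt","base","gamma",9096,5831,13166,3,"USD one-off","published"
"cost_docetaxel","base","gamma",26450,17570,38179,3,"USD per year","published"
"u_nrd","base","beta",0.9,0.84,0.96,4,"utility","published"
"u_nrd_after_local","base","beta",0.9,0.84,0.96,NA,"utility","published"
"u_loc_no_tx","base","beta",0.9,0.84,0.96,NA,"utility","published"
"u_loc_local_tx","base","beta",0.83,0.81,0.88,4,"utility","published"
"u_loc_systemic","base","beta",0.83,0.78,0.98,4,"utility","published"
"u_met_adt_arsi","base","beta",0.8,0.76,0.84,4,"utility","published"
"u_met_mdt","base","beta",0.72,0.69,0.75,4,"utility","published"
"u_mcrpc","base","beta",0.63,0.58,0.67,4,"utility","published"
"p_nrd_develop_disease","base","beta",0.15,0.1,0.21,2,"annual probability","placeholder"
"p_loc_progress_no_tx","base","beta",0.15,0.1,0.21,2,"annual probability","placeholder"
"p_loc_progress_local_tx","base","beta",0.08,0.05,0.12,2,"annual probability","placeholder"
"p_loc_progress_systemic","base","beta",0.1,0.06,0.15,2,"annual probability","placeholder"
"p_loc_local_cure","base","beta",0.25,0.17,0.34,2,"annual probability","placeholder"
"p_met_to_mcrpc","base","beta",0.2,0.14,0.27,2,"annual probability","placeholder"
"p_mcrpc_death","base","beta",0.3,0.21,0.4,2,"annual probability","placeholder"
"hr_mdt","base","lognormal",0.6,0.4,0.9,1,"hazard ratio","placeholder"
"tx_loc_no_treatment","base","beta",0.2,0.13,0.28,2,"proportion","placeholder"
"tx_loc_local","base","beta",0.6,0.49,0.7,2,"proportion","placeholder"
"tx_loc_systemic","base","beta",0.2,0.13,0.28,2,"proportion","placeholder"
"tx_met_adt_arsi","base","beta",0.8,0.7,0.88,2,"proportion","placeholder"
"tx_met_mdt","base","beta",0.2,0.12,0.3,2,"proportion","placeholder"
"share_mcrpc_arsi","base","fixed",0.5,NA,NA,NA,"proportion","placeholder"
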