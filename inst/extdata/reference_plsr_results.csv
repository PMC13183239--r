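split,group,trait,transformed,n_obs,n_cal,n_val,n_comp,rmse,r2,pct_rmse
cultivar,physiological,E,FALSE,173,137,36,3,1.04,0.19,19.77
cultivar,physiological,gs,FALSE,173,137,36,2,0.08,-0.02,26.67
cultivar,chemical,N,FALSE,163,127,36,3,0.28,0.35,21.19
cultivar,chemical,C,FALSE,162,126,36,1,0.71,0.14,25.38
cultivar,water_relations,Psi_pd,FALSE,172,136,36,4,1.55,-0.02,21.36
cultivar,water_relations,WUE_inst,TRUE,160,126,34,4,0.30,0.02,26.31
cultivar,water_relations,WUE_intr,TRUE,172,136,36,3,0.29,0.09,22.91
cultivar,morphological,Area,TRUE,168,132,36,1,0.19,0.26,20.11
cultivar,morphological,LDMC,TRUE,161,125,36,9,0.06,0.35,20.38
cultivar,morphological,LMA,TRUE,161,125,36,5,5.54,0.29,16.18
random,physiological,E,FALSE,173,138,35,2,1.03,0.28,20.12
random,physiological,Amax,FALSE,173,138,35,9,2.80,0.33,17.22
random,physiological,gs,FALSE,173,138,35,8,0.08,-0.03,25.92
random,chemical,N,FALSE,163,130,33,3,0.25,0.18,23.05
random,chemical,C,FALSE,162,129,33,2,0.69,0.17,21.71
random,water_relations,Psi_pd,FALSE,172,137,35,3,1.49,0.12,22.92
random,water_relations,WUE_intr,TRUE,173,138,35,4,0.27,0.04,24.66
random,water_relations,WUE_inst,TRUE,160,128,32,4,0.26,0.23,21.46
random,morphological,Area,TRUE,168,134,34,2,0.24,0.13,25.63
random,morphological,LDMC,TRUE,161,128,33,11,0.05,0.57,15.54
random,morphological,LMA,TRUE,161,128,33,5,0.08,-0.01,23.19
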