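trait,group,shapiro_w,median,mad,mean,sd,min,max,cv,prop_origin,prop_red_white,prop_cultivar,prop_row,prop_residual
E,physiological,0.991,NA,NA,3.24,1.13,0.68,6.14,34.83,0.42,0,0.38,0.08,0.13
Amax,physiological,0.988,NA,NA,21.83,3.35,12.95,30.35,15.35,0.27,0,0,0.19,0.53
gs,physiological,0.983,NA,NA,0.26,0.08,0.10,0.47,30.98,0,0,0.54,0.15,0.31
N,chemical,0.993,NA,NA,2.75,0.35,1.60,3.63,12.66,0,0.12,0,0.05,0.83
C,chemical,0.984,NA,NA,45.81,0.78,42.57,47.54,1.70,0.08,0,0.32,0,0.61
d13C,water_relations,0.983,NA,NA,-27.88,1.22,-30.86,-22.69,4.37,0,0,0,0.08,0.84
Psi_pd,water_relations,0.978,NA,NA,-5.88,1.47,-10.25,-1.25,24.95,0,0.18,0.21,0.07,0.55
WUE_intr,water_relations,0.986,85.51,25.07,NA,NA,44.90,174.94,29.32,0,0,0.52,0.15,0.33
WUE_inst,water_relations,0.925,6.70,2.28,NA,NA,3.59,28.98,33.98,0.59,0,0.29,0.04,0.08
Area,morphological,0.994,150.74,34.30,NA,NA,75.31,289.37,22.76,0.15,0,0.09,0,0.77
LDMC,morphological,0.811,255.69,21.98,NA,NA,163.95,568.35,8.60,0,0.09,0.05,0,0.86
LMA,morphological,0.905,70.51,6.75,NA,NA,38.53,122.61,9.57,0,0,0.04,0,0.96
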