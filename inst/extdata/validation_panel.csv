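response,pred_rsm_opt,cv_rsm_opt,pred_ann_opt,cv_ann_opt,exp_opt_milled,exp_opt_milled_sd,exp_opt_raw,exp_opt_raw_sd,pred_rsm_sub,cv_rsm_sub,pred_ann_sub,cv_ann_sub,exp_sub_milled,exp_sub_milled_sd,exp_sub_raw,exp_sub_raw_sd,free,free_sd,bound,bound_sd,total
TPC,6.56,3.5,5.83,11.8,6.89,0.13,6.31,0.46,5.70,1.4,4.97,8.2,5.59,0.06,3.94,0.13,15.99,1.16,2.39,0.29,18.38
TF,11.29,1.2,9.82,11.0,11.48,0.05,11.01,0.41,10.56,0.8,9.43,7.2,10.44,0.08,7.08,0.05,26.82,2.65,4.72,0.47,31.55
TFL,1.60,5.5,1.61,5.1,1.73,0.07,1.67,0.06,1.33,1.6,1.18,9.8,1.36,0.04,0.78,0.01,1.63,0.30,0.20,0.06,1.83
PAC,3.42,0.0,3.14,5.9,3.42,0.05,3.24,0.09,3.23,0.2,3.06,3.7,3.22,0.12,2.68,0.03,3.91,0.37,1.32,0.08,5.23
TPA,4.87,0.5,5.01,2.5,4.84,0.48,4.12,0.29,3.90,0.8,3.76,3.4,3.94,0.18,23.64,0.08,6.88,0.23,0.98,0.06,7.86
TOD,2.25,1.6,1.97,7.9,2.20,0.06,2.04,0.03,1.87,0.0,1.88,0.2,1.87,0.08,1.28,0.06,5.56,0.30,0.91,0.11,6.47
AC,23.64,0.7,22.69,2.3,23.42,0.15,22.36,0.24,21.12,0.8,19.35,7.0,21.36,0.66,14.99,0.18,22.79,1.54,5.31,0.42,28.10
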