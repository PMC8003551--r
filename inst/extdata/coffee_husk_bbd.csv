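run,temperature,time,acidity,sl_ratio,TPC,TPC_sd,TF,TF_sd,TFL,TFL_sd,PAC,PAC_sd,TPA,TPA_sd,TOD,TOD_sd,AC,AC_sd
1,30,5,1,0.035,4.19,0.12,5.52,0.27,0.74,0.14,2.48,0.25,1.28,0.08,0.86,0.11,11.95,0.08
2,100,5,1,0.035,5.45,0.12,7.94,0.25,0.84,0.07,2.63,0.22,2.29,0.11,1.23,0.06,15.61,0.05
3,30,90,1,0.035,4.41,0.09,6.30,0.24,0.73,0.08,2.34,0.09,1.69,0.18,1.03,0.10,11.90,0.09
4,100,90,1,0.035,5.44,0.10,7.34,0.18,0.96,0.08,2.74,0.13,2.42,0.06,1.28,0.06,15.37,0.07
5,65,47.5,0,0.02,4.47,0.13,8.60,0.23,1.09,0.12,2.99,0.27,2.98,0.16,1.56,0.10,17.43,0.05
6,65,47.5,2,0.02,4.56,0.13,6.38,0.34,0.71,0.03,3.48,0.11,1.55,0.07,1.13,0.05,10.32,0.05
7,65,47.5,0,0.05,3.47,0.15,6.99,0.30,0.75,0.05,2.23,0.26,1.95,0.07,1.10,0.05,13.19,0.05
8,65,47.5,2,0.05,4.07,0.10,5.97,0.28,0.70,0.05,2.45,0.30,1.43,0.06,1.00,0.06,11.33,0.09
9,65,47.5,1,0.035,3.70,0.16,6.81,0.30,0.65,0.09,2.51,0.18,1.77,0.08,0.97,0.05,12.17,0.09
10,30,47.5,1,0.02,3.94,0.15,6.69,0.34,0.67,0.05,2.41,0.15,1.37,0.12,1.04,0.06,11.09,0.08
11,100,47.5,1,0.02,5.93,0.15,10.07,0.24,1.10,0.10,3.04,0.19,2.88,0.10,1.56,0.05,18.67,0.08
12,30,47.5,1,0.05,3.64,0.12,6.17,0.25,0.66,0.09,2.16,0.09,1.69,0.15,0.92,0.08,11.28,0.08
13,100,47.5,1,0.05,4.07,0.17,7.32,0.28,0.78,0.06,2.22,0.27,2.19,0.08,1.06,0.05,13.47,0.06
14,65,5,0,0.035,4.30,0.21,7.09,0.34,0.76,0.06,2.51,0.20,2.14,0.13,1.26,0.04,16.20,0.08
15,65,90,0,0.035,4.27,0.25,7.60,0.27,0.97,0.09,2.55,0.13,2.74,0.10,1.58,0.07,17.33,0.08
16,65,5,2,0.035,4.50,0.23,6.89,0.35,0.63,0.14,2.47,0.16,1.54,0.06,1.11,0.06,12.52,0.07
17,65,90,2,0.035,4.18,0.10,5.55,0.12,0.75,0.09,2.67,0.25,1.53,0.18,1.06,0.07,10.44,0.06
18,65,47.5,1,0.035,3.68,0.10,6.00,0.21,0.69,0.14,2.52,0.16,1.74,0.11,0.94,0.06,12.04,0.09
19,30,47.5,0,0.035,4.22,0.10,7.06,0.27,0.79,0.10,2.49,0.18,2.23,0.06,1.26,0.07,15.55,0.04
20,100,47.5,0,0.035,4.88,0.14,10.10,0.27,1.26,0.09,2.89,0.19,3.93,0.15,1.85,0.07,18.77,0.09
21,30,47.5,2,0.035,3.28,0.12,6.54,0.19,0.60,0.06,2.22,0.12,1.28,0.08,0.95,0.04,9.90,0.06
22,100,47.5,2,0.035,5.00,0.11,8.38,0.21,0.85,0.06,2.88,0.29,2.53,0.08,1.29,0.07,14.12,0.06
23,65,5,1,0.02,4.40,0.12,7.47,0.18,0.76,0.10,2.59,0.22,2.09,0.19,1.03,0.04,13.99,0.07
24,65,90,1,0.02,5.52,0.08,8.15,0.22,0.82,0.09,2.66,0.14,1.89,0.05,1.18,0.05,13.09,0.07
25,65,5,1,0.05,3.89,0.12,7.10,0.18,0.65,0.09,2.25,0.13,1.58,0.07,0.97,0.04,12.76,0.06
26,65,90,1,0.05,3.58,0.15,6.67,0.20,0.51,0.14,2.08,0.35,1.19,0.10,0.72,0.04,10.00,0.09
27,65,47.5,1,0.035,3.69,0.07,6.79,0.17,0.69,0.11,2.59,0.14,1.82,0.07,0.94,0.05,12.45,0.08
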