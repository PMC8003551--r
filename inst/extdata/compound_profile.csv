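compound,class,rt_min,parent_mz,ms2_mz,opt_milled,opt_milled_sd,opt_raw,opt_raw_sd,sub_milled,sub_milled_sd,sub_raw,sub_raw_sd,free,free_sd,bound,bound_sd,total
Gallic acid,hydroxybenzoic acid,1.73,169,125,22.79,1.45,10.94,0.81,12.11,0.89,8.51,0.10,23.15,0.30,,,23.15
Protocatechuic acid,hydroxybenzoic acid,3.34,153,109,127.96,6.86,83.53,5.37,66.20,8.73,55.08,2.11,99.94,1.33,42.82,8.59,142.76
4-hydroxybenzoic acid,hydroxybenzoic acid,4.43,137,93,3.51,0.34,2.47,0.19,3.19,0.36,1.56,0.07,4.30,0.07,3.75,0.51,8.06
Vanillic acid,hydroxybenzoic acid,5.43,167,152,6.00,2.52,,,,,,,9.55,0.20,,,9.55
Syringic acid,hydroxybenzoic acid,5.96,197,182,,,,,0.20,0.03,,,1.66,0.10,0.20,0.01,1.86
Salicylic acid,hydroxybenzoic acid,8.96,137,93,0.81,0.03,0.90,0.08,0.22,0.04,,,1.19,0.02,0.25,0.03,1.43
Chlorogenic acid,hydroxycinnamic acid,5.38,353,191,905.67,18.50,747.17,36.10,840.04,30.79,669.54,40.06,1428.40,25.80,0.67,0.08,1429.07
Caffeic acid,hydroxycinnamic acid,5.48,179,135,15.16,0.51,10.51,1.07,14.00,1.50,9.35,0.11,26.21,0.79,89.93,9.73,116.14
p-coumaric acid,hydroxycinnamic acid,6.81,163,119,2.27,0.04,1.39,0.11,4.22,0.14,1.37,0.06,2.94,0.04,8.21,1.31,11.15
Ferulic acid,hydroxycinnamic acid,7.81,193,134,,,,,4.25,0.36,,,1.74,0.08,5.08,0.67,6.81
3-4-dihydroxyphenylacetic acid,phenylacetic acid,4.18,167,123,1.46,0.51,1.04,0.04,,,,,,,,,
(+)-catechin,flavan-3-ol monomer,5.22,289,245,0.45,0.05,,,0.31,0.03,,,30.31,0.28,0.58,0.08,30.89
(-)-epicatechin,flavan-3-ol monomer,6.27,289,245,4.71,0.51,1.45,0.06,,,,,25.07,0.23,0.64,0.05,25.71
Procyanidin B1,flavan-3-ol dimer,4.90,577,289,5.84,0.69,,,,,,,,,,,
Procyanidin B2,flavan-3-ol dimer,5.93,577,289,3.03,0.46,0.93,0.17,0.76,0.09,0.77,0.08,,,,,
Quercetin-3-O-glucoside,flavonol,8.34,463,301,15.03,0.96,8.89,1.17,10.45,0.73,10.39,0.44,18.16,0.42,0.66,0.03,18.82
Quercetin-3-O-galactoside,flavonol,8.65,463,301,14.33,0.14,8.79,0.42,10.20,1.91,10.25,0.26,18.17,0.41,0.67,0.05,18.84
Kaempferol-3-O-galactoside,flavonol,9.46,447,284,32.12,0.94,18.27,0.83,11.50,0.24,14.13,1.46,40.32,0.85,1.05,0.11,41.37
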