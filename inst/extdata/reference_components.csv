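parameter,CR,NRR56,CE,SB,GL
sigma2_ss,4.50e-3,5.41e-3,3.06e-4,1.96e-3,3.9844
sigma_ssd,1.47e-4,-3.80e-4,8.16e-5,8.90e-5,3.1303
sigma2_d,2.49e-3,3.03e-3,2.24e-3,2.08e-4,3.9699
sigma2_pess,4.13e-8,2.68e-4,2.22e-9,1.76e-7,1.16e-6
sigma2_ped,2.75e-7,4.09e-3,4.65e-7,3.09e-4,0.5436
sigma2_hym,0.0126,0.0152,0.0228,8.59e-3,3.2778
sigma2_e,0.2099,0.2003,0.0521,0.0140,27.1262
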