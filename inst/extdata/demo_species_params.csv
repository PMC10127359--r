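species,nesting_strategy,mean_dry_mass_mg,cv_dry_mass,mean_fwc,cv_fwc,mean_wlr_per_h,cv_wlr,mean_wlt_pct,cv_wlt,n_individuals
G_stercorarius,tunneler,247.8,0.45,2.18,0.30,0.008,0.30,50.9,0.15,38
O_fracticornis,tunneler,18.2,0.29,4.29,0.30,0.007,0.40,70.7,0.12,39
O_taurus,tunneler,21.2,0.28,2.06,0.30,0.008,0.45,64.5,0.15,16
E_fulvus,tunneler,18.4,0.22,2.42,0.30,0.012,0.45,69.7,0.09,15
S_schaefferi,roller,22.4,0.28,2.96,0.30,0.005,0.40,47.3,0.15,8
R_foetens,dweller,36.6,0.14,2.21,0.22,0.014,0.40,54.8,0.06,7
C_erraticus,dweller,8.2,0.18,2.40,0.30,0.018,0.40,62.0,0.15,7
B_rufa,dweller,13.0,0.11,2.34,0.30,0.009,0.35,50.2,0.15,7
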