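elevation,n_spp,mpd_observed,null_mean,null_sd,nri_printed,p_printed
1000,23,442.17,437.58,17.66,-0.26,0.61
1200,31,482.24,439.39,14.52,-2.95,1.00
1400,20,454.71,437.83,19.14,-0.88,0.80
1600,20,404.53,437.88,19.17,1.74,0.04
1800,20,401.75,438.65,19.49,1.89,0.03
2000,14,401.86,437.12,23.72,1.49,0.07
2200,3,276.25,437.42,72.82,2.21,0.02
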