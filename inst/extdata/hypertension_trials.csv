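study,n_treated,n_control,mean_base_treated,sd_base_treated,mean_base_control,sd_base_control,mean_final_treated,sd_final_treated,mean_final_control,sd_final_control,corr_treated,corr_control
ATMH,780,750,152.28,15.25,153.05,15.73,132.85,16.72,139.75,17.85,0.265,0.284
HEP,150,199,189.94,16.15,191.55,17.64,165.06,20.03,179.89,22.15,0.335,0.331
EWPHE,90,82,177.33,15.85,178.23,15.06,156.88,21.26,170.45,26.91,0.462,0.534
HDFP,2427,2370,151.68,19.83,151.00,19.53,130.09,19.25,138.54,21.26,0.337,0.408
MRC-1,3546,3445,156.60,16.09,156.65,15.96,135.49,16.32,144.25,17.58,0.346,0.416
MRC-2,1314,1337,182.19,12.63,182.13,12.73,153.99,20.13,164.58,19.71,0.178,0.137
SHEP,2365,2371,170.49,9.5,170.12,9.24,145.10,19.05,156.24,20.12,0.315,0.253
STOP,137,131,194.68,12.21,194.15,11.16,171.46,19.29,189.11,21.9,0.177,0.414
Sy-Chi,1252,1139,170.73,10.9,170.25,11.41,150.2,15.84,156.55,16.86,0.199,0.347
Sy-Eur,2398,2297,173.75,9.86,173.94,10.07,154.87,16.31,165.24,16.33,0.319,0.431
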