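participant_id,nights,mean_glucose_mean,mean_glucose_sd,sd_mean,sd_sd,cv_mean,cv_sd,tir_mean,tir_sd,t_hyper_mean,t_hyper_sd,t_hypo_mean,t_hypo_sd
HUPA001,13,181.71,32.27,67.12,10.97,37.27,5.07,54.21,13.77,43.54,14.74,2.25,3.13
HUPA002,11,113.68,30.59,50.18,15.85,44.72,11.52,60.94,16.59,15.00,17.30,24.07,18.09
HUPA003,12,139.88,22.85,55.38,16.57,38.98,5.56,69.66,12.53,22.69,14.68,7.65,7.24
HUPA004,10,178.75,44.75,74.15,23.86,44.07,14.86,44.37,19.36,43.70,22.39,11.93,13.73
HUPA005,8,151.06,23.74,43.05,14.68,29.29,11.12,69.09,16.96,27.21,18.19,3.70,4.45
HUPA006,6,212.05,97.73,62.41,36.48,35.97,20.23,46.76,28.69,48.68,29.74,4.56,5.55
HUPA007,13,173.64,29.53,73.14,14.31,42.53,8.47,46.28,17.35,45.07,17.61,8.65,8.49
HUPA011,13,159.30,19.37,54.00,8.38,34.09,4.97,65.47,10.23,31.96,11.56,2.57,3.52
HUPA014,12,186.47,19.12,68.55,22.54,36.68,11.00,44.96,10.21,50.83,11.34,4.20,3.77
HUPA015,13,165.90,20.72,65.03,10.67,39.33,5.08,57.68,12.01,38.60,13.38,3.72,3.22
HUPA016,13,157.32,45.81,67.24,20.44,43.51,12.62,51.16,18.54,36.10,22.75,12.74,10.33
HUPA017,13,198.39,27.38,62.06,16.51,31.67,8.14,37.39,16.94,60.25,18.30,2.35,3.36
HUPA018,11,144.12,35.97,62.64,17.93,43.60,5.62,49.73,11.83,31.77,18.56,18.50,14.91
HUPA019,6,159.97,17.59,54.82,5.05,34.40,2.64,59.14,11.14,36.85,11.92,4.01,2.24
HUPA020,10,193.99,29.73,72.11,18.31,37.23,7.74,44.92,14.04,51.29,15.31,3.78,3.88
HUPA021,8,141.27,14.84,44.83,5.46,31.92,4.32,74.07,9.15,22.78,10.68,3.14,5.71
HUPA022,14,111.12,23.51,31.58,7.55,29.00,6.96,79.57,11.25,5.01,8.62,15.42,13.42
HUPA023,10,132.89,21.29,38.98,7.22,29.53,4.81,78.92,12.69,18.05,14.39,3.03,4.47
HUPA024,6,157.51,31.58,56.53,18.80,37.25,14.74,57.63,9.82,35.17,15.25,7.19,10.08
HUPA025,12,113.51,14.56,36.46,9.21,32.09,7.44,79.58,11.24,7.42,6.85,12.99,8.94
HUPA026,16,133.64,24.60,57.68,20.78,42.86,11.98,60.70,21.91,22.25,17.37,17.05,13.76
HUPA027,13,121.24,21.16,30.73,8.24,25.82,7.92,87.04,18.09,8.36,18.09,4.60,4.91
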