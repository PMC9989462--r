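participant_id,nights,good,poor,sleep_hours_mean,sleep_hours_sd,efficiency_mean,efficiency_sd,waso_mean,waso_sd,awakenings_mean,awakenings_sd
HUPA001,13,3,10,6.81,2.11,94.08,2.14,42.38,13.93,5.00,2.24
HUPA002,11,8,3,7.07,1.45,97.45,1.63,33.36,14.53,2.73,1.90
HUPA003,12,7,5,6.35,1.99,93.08,2.81,45.25,22.8,3.25,1.76
HUPA004,10,6,4,6.22,0.75,95.80,1.81,40.10,7.75,3.20,1.40
HUPA005,8,0,8,6.69,0.97,58.50,14.41,50.38,10.68,3.50,1.51
HUPA006,6,0,6,7.54,0.98,47.67,33.68,68.33,22.44,6.33,3.33
HUPA007,13,8,5,6.06,0.68,94.08,2.10,37.92,7.76,2.69,1.49
HUPA011,13,1,12,7.37,0.72,90.92,3.43,55.92,11.84,4.23,1.83
HUPA014,12,1,11,9.48,2.12,92.67,2.39,86.75,35.94,5.08,2.50
HUPA015,13,3,10,7.94,1.76,93.69,1.55,54.23,21.19,3.69,1.49
HUPA016,13,2,11,7.91,0.80,96.54,2.22,53.08,16.17,0.15,0.38
HUPA017,13,1,12,7.85,1.11,90.31,3.35,66.00,19.94,4.85,1.68
HUPA018,11,0,11,7.67,0.69,46.91,5.49,51.64,9.64,4.09,1.14
HUPA019,6,0,6,7.06,0.87,93.00,1.67,60.33,19.25,6.17,5.00
HUPA020,10,0,10,6.14,1.57,46.50,9.16,48.7,19.97,3.70,1.25
HUPA021,8,0,8,7.40,0.47,69.38,2.20,56.88,13.29,4.62,1.85
HUPA022,14,8,6,5.76,1.54,93.93,2.97,41.86,13.40,3.50,1.56
HUPA023,10,0,10,7.93,1.33,95.50,1.18,55.10,9.35,4.80,1.40
HUPA024,6,1,5,5.90,1.38,92.00,4.47,56.17,16.34,1.17,2.86
HUPA025,12,1,11,7.32,1.01,92.08,3.00,55.75,13.14,4.17,2.52
HUPA026,16,0,16,8.22,0.71,60.75,5.86,55.88,12.10,5.31,1.82
HUPA027,13,4,9,6.52,0.81,93.38,2.33,45.85,11.12,3.23,1.54
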