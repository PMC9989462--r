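participant_id,light_pct,deep_pct,rem_pct
HUPA001,54.85,12.49,22.23
HUPA002,50.23,20.19,21.88
HUPA003,59.51,12.68,16.36
HUPA004,55.71,17.98,15.47
HUPA005,53.25,16.93,17.19
HUPA006,51.74,14.55,18.74
HUPA007,56.18,15.01,18.33
HUPA011,57.72,12.72,16.85
HUPA014,52.26,14.00,18.88
HUPA015,52.07,15.76,20.00
HUPA016,53.85,13.26,20.88
HUPA017,51.83,13.51,20.76
HUPA018,45.00,16.56,27.24
HUPA019,60.80,16.55,8.62
HUPA020,54.46,15.25,17.30
HUPA021,54.44,13.65,19.17
HUPA022,59.13,11.72,17.05
HUPA023,58.11,15.43,14.81
HUPA024,59.81,10.19,14.20
HUPA025,52.66,16.63,18.07
HUPA026,49.04,16.83,22.83
HUPA027,48.32,19.87,19.94
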