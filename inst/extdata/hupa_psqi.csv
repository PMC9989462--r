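participant_id,quality,latency,duration,efficiency,disturbances,medication,daytime_dysfunction,subjective_hours
HUPA001,3,3,1,0,3,0,3,6
HUPA002,0,1,1,0,1,1,2,7
HUPA003,3,2,3,0,2,0,2,5
HUPA004,0,1,0,0,1,3,2,8
HUPA005,1,1,1,0,2,0,0,7
HUPA006,0,1,1,1,1,0,2,6.3
HUPA007,0,1,1,0,1,1,1,7
HUPA008,0,1,2,0,1,1,1,5
HUPA009,0,1,1,0,1,0,2,6.3
HUPA010,2,3,3,3,2,0,3,4
HUPA011,1,1,0,0,1,0,1,7.3
HUPA014,2,2,1,3,2,0,0,7
HUPA015,1,0,0,0,1,0,1,6.3
HUPA016,1,1,0,0,1,0,0,7.3
HUPA017,2,1,3,3,2,0,3,4.3
HUPA018,2,1,1,1,1,0,1,5
HUPA019,1,1,0,0,1,0,0,10
HUPA020,0,1,0,0,1,0,1,6.3
HUPA021,3,3,1,1,2,0,0,6
HUPA022,0,NA,0,NA,NA,0,1,6
HUPA023,0,2,0,0,1,0,0,8.3
HUPA024,0,3,2,1,1,0,0,5
HUPA025,0,0,1,2,1,1,0,6
HUPA026,1,1,0,0,2,3,1,8
HUPA027,1,1,0,0,1,0,0,7.5
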