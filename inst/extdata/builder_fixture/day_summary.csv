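"participant_id","date","wear_min_awake","has_valid_sleep","valid"
"P1",2023-03-01,720,TRUE,TRUE
"P1",2023-03-02,720,TRUE,TRUE
"P1",2023-03-03,720,TRUE,TRUE
"P1",2023-03-04,720,TRUE,TRUE
"P1",2023-03-05,720,TRUE,TRUE
"P1",2023-03-06,720,TRUE,TRUE
"P1",2023-03-07,720,TRUE,TRUE
"P1",2023-03-08,720,TRUE,TRUE
"P2",2023-03-01,650,TRUE,TRUE
"P2",2023-03-02,650,TRUE,TRUE
"P2",2023-03-03,650,TRUE,TRUE
"P2",2023-03-04,650,TRUE,TRUE
"P2",2023-03-05,0,FALSE,FALSE
"P2",2023-03-06,0,FALSE,FALSE
"P2",2023-03-07,0,FALSE,FALSE
"P2",2023-03-08,0,FALSE,FALSE
"P3",2023-03-01,650,TRUE,TRUE
"P3",2023-03-02,600,TRUE,TRUE
"P3",2023-03-03,700,TRUE,TRUE
"P3",2023-03-04,599,TRUE,FALSE
"P3",2023-03-05,599,TRUE,FALSE
"P3",2023-03-06,599,TRUE,FALSE
"P3",2023-03-07,599,TRUE,FALSE
"P3",2023-03-08,599,TRUE,FALSE
"P4",2023-03-01,600,TRUE,TRUE
"P4",2023-03-02,600,TRUE,TRUE
"P4",2023-03-03,599,TRUE,FALSE
"P4",2023-03-04,600,TRUE,TRUE
"P4",2023-03-05,599,TRUE,FALSE
"P4",2023-03-06,600,TRUE,TRUE
"P4",2023-03-07,599,TRUE,FALSE
"P4",2023-03-08,600,TRUE,TRUE
"P5",2023-03-01,700,TRUE,TRUE
"P5",2023-03-02,700,TRUE,TRUE
"P5",2023-03-03,700,TRUE,TRUE
"P5",2023-03-04,700,FALSE,FALSE
"P5",2023-03-05,700,TRUE,TRUE
"P5",2023-03-06,700,TRUE,TRUE
"P5",2023-03-07,700,TRUE,TRUE
"P5",2023-03-08,700,FALSE,FALSE
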