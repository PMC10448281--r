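"participant_id","date","item_1","item_2","item_3","item_4","item_5","item_6","item_7","item_8","item_9","item_10","item_11","item_12"
"P1",2023-03-08,4,4,4,1,3,1,1,1,1,1,1,1
"P2",2023-03-08,3,4,1,1,1,1,1,1,1,1,1,1
"P3",2023-03-08,4,4,4,1,4,1,1,1,1,1,1,1
"P4",2023-03-08,4,4,4,1,1,1,1,1,1,1,1,1
"P5",2023-03-08,4,4,2,1,1,1,1,1,1,1,1,1
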