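trial_id,n,all_ae,serious,deaths
SYN-001,120,90,12,0
SYN-002,250,180,30,2
SYN-003,80,60,9,1
SYN-004,400,290,41,0
SYN-005,150,110,16,0
SYN-006,300,215,33,1
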