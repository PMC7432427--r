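aoi,duration_ms
D,220
E,180
D,240
F,130
D,210
E,175
H,120
D,230
E,190
D,200
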