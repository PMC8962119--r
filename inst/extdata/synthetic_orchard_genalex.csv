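7,25,2,10,15
synthetic orchard example (generated; not real data),,,PT,HC
id,group,L01,,L02,,L03,,L04,,L05,,L06,,L07,
M001,PT,104,104,104,104,103,108,106,106,112,112,101,106,105,107
M002,PT,101,103,104,104,107,110,104,106,103,109,105,105,105,105
M003,PT,103,104,104,107,106,107,103,106,112,112,106,106,101,105
M004,PT,103,104,104,107,106,106,105,105,112,113,104,106,103,107
M005,PT,103,104,104,107,101,106,108,108,103,104,104,106,103,105
M006,PT,103,104,104,104,103,106,105,106,112,112,106,106,103,106
M007,PT,101,104,104,104,103,106,103,105,104,112,101,106,103,103
M008,PT,104,104,101,104,103,110,103,104,103,107,105,106,103,105
M009,PT,104,104,104,104,104,106,103,108,108,112,101,104,105,107
M010,PT,103,103,101,107,106,107,105,105,112,112,105,106,103,105
hc0001,HC,103,104,104,107,103,106,105,106,112,112,106,106,103,105
hc0002,HC,104,104,104,104,106,106,105,105,104,114,106,106,103,103
hc0003,HC,104,104,104,104,106,106,104,106,112,112,106,106,103,103
hc0004,HC,103,104,104,104,103,106,104,106,112,112,102,106,105,106
hc0005,HC,103,104,104,104,103,107,104,106,112,112,105,106,103,105
hc0006,HC,101,104,104,104,106,107,103,108,108,112,101,106,101,105
hc0007,HC,103,103,104,107,106,106,103,106,112,112,106,106,103,105
hc0008,HC,104,104,104,104,106,108,105,106,103,112,101,101,105,106
hc0009,HC,101,104,104,104,103,107,106,106,103,108,105,106,105,105
hc0010,HC,103,104,104,107,106,110,104,108,103,112,104,106,105,105
hc0011,HC,104,104,104,104,106,107,103,105,112,112,104,104,105,105
hc0012,HC,104,104,104,107,103,106,104,108,108,108,101,104,105,105
hc0013,HC,103,104,104,104,106,106,105,105,111,112,104,104,103,106
hc0014,HC,103,104,104,104,103,106,105,106,108,112,105,106,103,103
hc0015,HC,104,104,101,104,103,110,103,104,103,107,104,105,103,105
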