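scope,category,count
hk,CR,35
hk,EN,17
hk,VU,24
hk,NT,8
hk,LC,30
hk,DD,4
hk,RE,17
hk,NA,3
cn,CR,5
cn,EN,16
cn,VU,22
cn,NT,13
cn,LC,70
cn,DD,4
cn,NA,8
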