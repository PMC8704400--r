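predicted,ST,WL,MR,TJ,LJ,RJ
ST,591,4,1,4,0,0
WL,7,551,39,3,0,NA
MR,1,42,360,71,121,120
TJ,1,0,32,456,50,55
LJ,0,2,101,39,328,121
RJ,0,1,67,27,101,303
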