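predicted,ST,WL,MR,TJ,LJ,RJ
ST,581,3,0,3,0,0
WL,8,578,65,3,2,5
MR,1,16,379,13,95,83
TJ,4,1,9,479,32,30
LJ,0,2,88,64,422,91
RJ,0,0,59,38,50,391
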