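label,precision,recall,f_measure
ST,98.5,98.5,98.5
WL,91.7,91.8,91.8
MR,50.3,60.0,54.8
TJ,76.8,76.0,76.4
LJ,55.5,54.7,55.1
RJ,60.7,50.5,55.1
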