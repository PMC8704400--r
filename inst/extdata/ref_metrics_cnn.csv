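label,precision,recall,f_measure
ST,99.0,97.8,98.4
WL,87.4,96.3,91.7
MR,64.6,63.2,63.9
TJ,86.5,79.8,83.0
LJ,63.3,70.3,66.6
RJ,72.7,65.2,68.7
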