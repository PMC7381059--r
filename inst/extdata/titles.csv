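title
DR
MR
MRS
MS
MISS
MX
PROF
REV
SIR
LADY
JR
SR
JNR
SNR
II
III
ESQ
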