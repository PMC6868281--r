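marker,pos_a,n_a,pos_b,n_b
TBX21,252,283,419,2295
IFNG,107,293,54,2295
PRF1,146,283,108,2295
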