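marker,pos_a,n_a,pos_b,n_b
PRF1,9,22,17,21
TGFB1,4,22,15,21
IFNG,17,22,2,21
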