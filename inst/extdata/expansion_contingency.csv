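tetramer,controls_expanded,controls_total,cases_expanded,cases_total
All,134,2660,117,2843
HCRT1-13,74,1141,71,1143
HCRT25-37,2,384,0,576
HCRT56-69,52,384,20,384
HCRT87-100,6,751,26,740
HCRT87-100 (excl. TIV),0,463,24,644
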