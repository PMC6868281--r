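quantity,numerator,denominator
wells_with_tcr,4605,5503
cross_binding_expanded_clonotypes,34,52
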