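# decision-rubric cut-offs; set per risk tolerance
dispersal_high_min: 1.8
response_ratio_high_min: 0.4
ci_high_min_abs: 0.5
min_worms: 101
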