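treatment	n_populations	cumulative_mutations	day90_mutations	fixed_mutations
biofilm	3	535	382	48
planktonic	3	339	201	5
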