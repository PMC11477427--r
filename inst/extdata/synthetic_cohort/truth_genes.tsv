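gene_id	n_carriers	mode	beta	carrier_frac
PLT001	9	deep_amp	1.5	0.15
PLT002	9	deep_amp	1.5	0.15
PLT003	9	deep_amp	1.5	0.15
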