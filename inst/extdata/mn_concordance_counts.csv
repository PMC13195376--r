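condition,band,n_within,n_tracts
diabetes,0.10,605,1500
hypertension,0.10,635,1500
diabetes,0.25,1168,1500
hypertension,0.25,1195,1500
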