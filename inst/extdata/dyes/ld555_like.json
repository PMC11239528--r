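{
 "name": "LD555-like",
 "epsilon": 150000,
 "k_em": 250000000.0,
 "k_nr": 720000000.0,
 "k_ISC": 30000000.0,
 "k_TR": 909090.9090909091,
 "eta": 0.2,
 "notes": "Triplet lifetime (1.1 us) is a reported value; singlet rates mirror the Cy3-like defaults (self-healing dyes share the cyanine core)."
}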