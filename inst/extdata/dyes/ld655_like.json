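{
 "name": "LD655-like",
 "epsilon": 10000,
 "k_em": 200000000.0,
 "k_nr": 446666666.6666666,
 "k_ISC": 20000000.0,
 "k_TR": 5000000.0,
 "eta": 0.2,
 "notes": "Triplet lifetime (0.20 us) is a reported value; singlet rates mirror the Cy5-like defaults."
}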