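{
 "name": "Cy3-like",
 "epsilon": 150000,
 "k_em": 250000000.0,
 "k_nr": 720000000.0,
 "k_ISC": 30000000.0,
 "k_TR": 32258.06451612903,
 "eta": 0.2,
 "notes": "Triplet lifetime (31 us, deoxygenated) is a reported value; singlet rates are literature-typical defaults (tau_fl 1.0 ns, phi 0.25) with the effective ISC yield (0.03) calibrated so the nine-state model reproduces the reported magnitude of the illumination-dependent FRET decrease for this pair."
}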