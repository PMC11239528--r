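{
 "name": "Cy5-like",
 "epsilon": 10000,
 "k_em": 200000000.0,
 "k_nr": 446666666.6666666,
 "k_ISC": 20000000.0,
 "k_TR": 19607.843137254902,
 "eta": 0.2,
 "notes": "Triplet lifetime (51 us, deoxygenated) is a reported value; singlet rates are literature-typical defaults (tau_fl 1.5 ns, phi 0.30) with the effective ISC yield (0.03) calibrated jointly with the donor. epsilon is at 532 nm (far off-peak)."
}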