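{
 "donor": "cy3_like",
 "acceptor": "ld655_like",
 "R0": 56.0,
 "R": 60.23
}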