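nt_sep	R_A
5	40.63
8	45.84
11	52.54
14	60.23
17	68.57
20	77.37
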