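pressure	resistance_kohm	conductance
0	721.49	0
0.01	21.34	0.05
0.02	4.87	0.21
0.04	2.51	0.40
0.06	1.97	0.51
0.08	1.41	0.71
0.1	1.11	0.9
0.12	1.02	0.98
0.16	0.89	1.12
0.2	0.73	1.37
0.25	0.56	1.79
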