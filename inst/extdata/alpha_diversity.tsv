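treatment	bacteria_ace	bacteria_ace_se	bacteria_simpson	bacteria_simpson_se	fungi_ace	fungi_ace_se	fungi_simpson	fungi_simpson_se
P0	1569.41	18.96	0.998	0.000	383.35	26.86	0.956	0.012
P1	1611.93	60.33	0.998	0.000	375.72	23.98	0.962	0.018
P2	1646.28	18.83	0.997	0.001	384.27	39.91	0.942	0.043
P3	1552.56	85.05	0.997	0.000	387.01	26.39	0.963	0.004
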