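treatment	stem_number	stem_number_se	biomass	biomass_se	height	height_se
P0	551.70	11.14	457.20	15.29	54.68	1.20
P1	792.75	33.30	503.85	9.95	61.45	0.73
P2	810.47	11.89	559.97	29.62	62.18	1.31
P3	854.90	12.08	567.10	21.09	67.28	1.61
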