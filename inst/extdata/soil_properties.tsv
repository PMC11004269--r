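treatment	pH	pH_se	EC	EC_se	AP	AP_se	AN	AN_se	AK	AK_se
P0	8.04	0.06	223.30	17.63	15.34	4.08	46.10	3.63	171.91	6.149
P1	8.05	0.02	188.16	11.98	24.24	2.93	47.23	2.49	197.63	8.06
P2	8.08	0.02	227.23	37.08	25.02	1.00	54.15	4.02	190.15	23.53
P3	8.09	0.01	199.07	30.67	36.45	3.26	56.46	5.67	177.56	7.40
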