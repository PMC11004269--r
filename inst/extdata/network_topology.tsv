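treatment	edges	num_pos_edges	num_neg_edges	positive_pct	nodes	bacteria_nodes	fungus_nodes	edge_density	average_degree	average_path_length	degree_centralization	betweenness_centralization	closeness_centralization
P0	11846	6173	5673	52.11	592	505	87	0.068	40.02	1.78	0.30	0.0053	0.65
P1	12176	6285	5891	51.62	598	511	87	0.068	40.72	1.75	0.21	0.0023	0.74
P2	13961	8181	5780	58.60	597	511	86	0.078	46.77	1.75	0.26	0.0039	0.83
P3	11978	6026	5952	50.31	598	512	86	0.067	40.06	1.77	0.29	0.0035	0.64
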