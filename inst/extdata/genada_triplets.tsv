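snp1	snp2	snp3	t_ig	p_value	perm_p
rs17793957	rs605928	rs9911460	8.50	0.003	0.001
rs7045548	rs1795977	rs11652714	8.25	0.004	0.001
rs1879019	rs17081694	rs605928	6.65	0.009	0.002
rs1608169	rs11862388	rs16993582	7.14	0.007	0.003
rs4895529	rs9314604	rs17081694	8.47	0.003	0.006
rs17067596	rs9314604	rs17081694	8.46	0.003	0.008
rs10050568	rs2978012	rs6098412	7.76	0.005	0.015
rs1879019	rs1519959	rs136687	8.48	0.003	0.036
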