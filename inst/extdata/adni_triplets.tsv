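snp1	snp2	snp3	t_ig	p_value	perm_p
rs9366664	rs3780792	rs1150360	8.53	0.003	0.001
rs6705017	rs10017010	rs557098	7.51	0.006	0.001
rs11749731	rs3780792	rs7157639	6.74	0.009	0.001
rs1023276	rs324389	rs2824808	8.81	0.002	0.002
rs6751810	rs4561856	rs1023276	7.92	0.004	0.002
rs4561856	rs4409091	rs2633466	7.61	0.005	0.002
rs4561856	rs10807701	rs2824808	7.55	0.005	0.002
rs7091014	rs11006011	rs2633466	7.47	0.006	0.002
rs6856771	rs7157639	rs2824808	8.18	0.004	0.003
rs9366664	rs10960174	rs1150360	7.69	0.005	0.003
rs11749731	rs10807701	rs7157639	7.42	0.006	0.003
rs6705017	rs11006011	rs2633466	7.77	0.005	0.005
rs9313264	rs12056012	rs2633466	7.69	0.005	0.005
rs6705017	rs2633466	rs462074	7.38	0.006	0.006
rs10017010	rs9313264	rs2207851	8.65	0.003	0.008
rs4561856	rs9896368	rs2824808	8.88	0.002	0.009
rs4561856	rs7157639	rs717840	7.784	0.005	0.022
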