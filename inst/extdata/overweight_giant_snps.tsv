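snp_id	gene	chrom	pos	effect_allele	other_allele	eaf	beta	se	pval
rs10182181	ADCY3	2	25150296	G	A	0.50	0.057	0.009	2.10e-10
rs10853932	KCTD15	19	34310210	C	T	0.69	0.067	0.011	1.30e-09
rs12444979	GPRC5B	16	19935389	T	C	0.06	-0.079	0.013	1.80e-09
rs12623218	TMEM18	2	630300	A	T	0.88	0.110	0.012	5.80e-22
rs13130484	GNPDA2	4	45175691	T	C	0.42	0.071	0.009	3.90e-14
rs1421085	FTO	16	53800954	C	T	0.45	0.140	0.009	5.80e-50
rs2030323	BDNF	11	27694241	C	A	0.78	0.079	0.011	1.10e-12
rs2206277	TFAP2B	6	50798526	T	C	0.10	0.080	0.012	5.60e-12
rs2568958	NEGR1	1	72765116	A	G	0.65	0.062	0.009	1.10e-11
rs2596125	HNF4G	8	76565284	T	C	0.44	-0.052	0.009	5.90e-09
rs523288	MC4R	18	57834278	T	A	0.29	0.099	0.011	1.70e-20
rs633715	SEC16B	1	177815337	C	T	0.27	0.078	0.011	4.00e-12
rs8028313	MAP2K5	15	68056553	G	C	0.22	-0.065	0.011	2.00e-09
rs9816226	ETV5	3	185834290	T	A	0.85	0.070	0.012	2.00e-09
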