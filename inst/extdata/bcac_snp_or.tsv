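rsid	chrom	pos	effect_allele	other_allele	eaf	or	ci_low	ci_high	p
rs1558902	16	53803574	A	T	0.41	0.93	0.91	0.95	2.77e-14
rs713586	2	25158008	C	T	0.47	0.94	0.92	0.97	1.82e-06
rs7903146	10	114758349	C	T	0.72	0.96	0.94	0.98	7.01e-05
rs7599312	2	213413231	G	A	0.72	0.96	0.94	0.98	0.0004
rs17024393	1	110154688	C	T	0.03	0.93	0.87	0.98	0.007
rs2867125	2	622827	C	T	0.83	0.96	0.94	0.99	0.003
rs2287019	19	46202172	C	T	0.79	0.96	0.93	0.99	0.009
rs3810291	19	47569003	A	G	0.67	0.98	0.95	1.00	0.01
rs571312	18	57839769	A	C	0.24	0.97	0.95	1.00	0.02
rs543874	1	177889480	G	A	0.19	0.97	0.95	1.00	0.04
rs12401738	1	78446761	A	G	0.38	0.98	0.96	1.00	0.05
rs1528435	2	181550962	T	C	0.62	0.97	0.95	0.99	0.01
rs2112347	5	75015242	T	G	0.63	0.98	0.96	1.00	0.03
rs10733682	9	129460914	A	G	0.49	0.97	0.95	0.99	0.009
rs13191362	6	163033350	A	G	0.88	1.03	1.00	1.06	0.047
rs17405819	8	76806584	T	C	0.69	0.97	0.95	1.00	0.02
rs3736485	15	51748610	A	G	0.47	0.98	0.96	1.00	0.12
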