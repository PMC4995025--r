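rsid	effect_allele	other_allele	eaf	or	ci_low	ci_high	p
rs1558902	A	T	0.68	0.95	0.91	0.99	0.008
rs713586	C	T	0.48	0.96	0.93	1.00	0.03
rs7903146	C	T	0.70	0.96	0.92	1.00	0.04
rs7599312	G	A	0.96	0.94	0.84	1.03	0.17
rs17024393	C	T	0.41	0.96	0.92	0.99	0.009
rs2867125	C	T	0.64	0.97	0.94	1.00	0.07
rs2287019	C	T	0.80	0.96	0.92	1.00	0.06
rs3810291	A	G	0.43	0.96	0.92	0.99	0.01
rs571312	A	C	0.23	0.96	0.92	1.00	0.04
rs543874	G	A	0.20	0.96	0.92	1.00	0.04
rs12401738	A	G	0.38	0.96	0.93	1.00	0.05
rs1528435	T	C	0.63	0.98	0.94	1.01	0.22
rs2112347	T	G	0.44	0.97	0.94	1.00	0.08
rs10733682	A	G	0.47	0.99	0.95	1.02	0.41
rs13191362	A	G	0.87	1.04	0.98	1.09	0.18
rs17405819	T	C	0.69	0.99	0.95	1.02	0.5
rs3736485	A	G	0.43	0.98	0.94	1.01	0.15
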