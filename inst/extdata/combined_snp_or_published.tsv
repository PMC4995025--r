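rsid	or	ci_low	ci_high	p
rs1558902	0.93	0.91	0.95	3.63e-16
rs713586	0.95	0.93	0.97	3.19e-07
rs7903146	0.96	0.94	0.98	8.65e-06
rs7599312	0.96	0.94	0.98	0.0002
rs17024393	0.94	0.91	0.97	0.0003
rs2867125	0.96	0.94	0.99	0.0008
rs2287019	0.96	0.94	0.99	0.0010
rs3810291	0.97	0.95	0.99	0.002
rs571312	0.97	0.95	0.99	0.002
rs543874	0.97	0.95	0.99	0.005
rs12401738	0.97	0.96	0.99	0.008
rs1528435	0.97	0.96	0.99	0.008
rs2112347	0.98	0.96	0.99	0.008
rs10733682	0.98	0.96	0.99	0.01
rs13191362	1.03	1.01	1.06	0.02
rs17405819	0.98	0.96	1.00	0.02
rs3736485	0.98	0.96	1.00	0.04
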