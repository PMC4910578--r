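accession	ligand	het_code	expected_class	boldface
4COF	benzamidine	BEN	1	yes
3RIF	glutamate	.	1	no
3JAD	strychnine	.	1	no
3JAE	glycine	.	1	no
5CFB	strychnine	.	1	no
2BYR	methyllycaconitine	.	1	no
2BYS	lobeline	.	1	no
4BFQ	VUF9432	.	1	no
5AFJ	lobeline	.	1	yes
4A97	R-zopiclone	.	1	no
4A98	Br-flurazepam	.	1	no
4F8H	R-ketamine	.	2	yes
5AFJ	fragment-1	.	2	yes
2YN6	barium	BA	3	yes
2YOE	flurazepam	.	4	yes
2YN6	barium	BA	4	yes
5AFM	fragment-4	.	4	yes
3ZKR	bromoform	.	5	yes
5AFJ	fragment-1	.	6	yes
4HFD	bromoform	.	7	yes
4HFC	Br-ethanol	.	7	yes
4HFE	ethanol	.	7	yes
3RIF	avermectin	.	7	yes
3RI5	avermectin	.	7	no
3RIA	avermectin	.	7	no
3RHW	avermectin	.	7	no
4TNW	POPC	.	7	yes
3JAF	avermectin	.	7	no
3P4W	desflurane	.	8	yes
3P50	propofol	.	8	yes
4HFD	bromoform	.	8	yes
4HFH	bromoform	.	8	yes
3ZKR	bromoform	.	9	yes
3EAM	lipid	.	10	yes
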