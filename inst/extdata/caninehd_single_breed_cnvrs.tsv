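cnvr_id	chrom	start	end	length	n_genes	type	breed	n_affected	n_screened	freq	genes
78	21	40580407	40742936	162529	1	del	Finnish Spitz	4	12	0.33	PDE3B
2	1	65361010	65528809	167799	1	del	Elkhound	2	12	0.17	TRDN
16	3	93757480	94035855	278375	2	dupl	English Bulldog	2	12	0.17	ANAPC13,LCORL
23	4	82705831	82993500	287669	0	del	Weimaraner	8	26	0.31
37	8	28122926	28265491	142565	0	del	Greenland Sledge	3	12	0.25
47	13	14209388	14411209	201821	0	del	Brittany Spaniel	5	12	0.42
48	13	21103428	22714370	1610942	11	dupl	Standard Poodle	2	12	0.17	DSCC1,TNFRSF11B,ENPP2,COLEC10,NOV,TAF2,MRPL13,DEPTOR,COL14A1,MTBP,SNTB1
57	15	37836364	37940678	104314	1	dupl	Shar Pei	2	11	0.18	NDUFA12
58	16	45458552	45682702	224150	0	del	Border Collie	2	9	0.22
68	19	13325414	13514903	189489	0	del	Eurasian	3	11	0.27
69	19	13816712	15228649	1411937	3	dupl	Shar Pei	2	11	0.18	C4ORF33,SCLT1,PHF17
71	19	29002373	30541395	1539022	1	dupl	Border Collie	3	9	0.33	CNTNAP5
82	22	21232747	21306657	73910	0	dupl	Eurasian	3	11	0.27
96	32	37679695	37939968	260273	0	del	Dalmatian	2	7	0.29
103	35	23792470	23921812	129342	0	del	German Shepherd	3	11	0.27
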