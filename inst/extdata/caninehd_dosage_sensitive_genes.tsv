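cnvr_id	chrom	start	end	type	gene	breed
2	1	65361010	65528809	del	TRDN	Elkhound
16	3	93757480	94035855	dupl	ANAPC13	English Bulldog
16	3	93757480	94035855	dupl	LCORL	English Bulldog
21	4	74490811	74617835	dupl	NUP155	Golden Retriever,Labrador Retriever,Flat-coated Retriever
21	4	74490811	74617835	dupl	WDR70	Golden Retriever,Labrador Retriever,Flat-coated Retriever
25	4	87386509	87831380	dupl	CDH18	Dachshund
41	11	12650626	13811903	dupl	PRR16	Bernese Mountain dog
52	14	5305030	5752740	del/dupl	OR14C36	25 breeds
52	14	5305030	5752740	del/dupl	OR14I1	25 breeds
52	14	5305030	5752740	del/dupl	OR2T1	25 breeds
52	14	5305030	5752740	del/dupl	OR2T11	25 breeds
52	14	5305030	5752740	del/dupl	OR2T2	25 breeds
52	14	5305030	5752740	del/dupl	OR2T27	25 breeds
52	14	5305030	5752740	del/dupl	OR2T29	25 breeds
52	14	5305030	5752740	del/dupl	OR2T35	25 breeds
52	14	5305030	5752740	del/dupl	OR2T4	25 breeds
52	14	5305030	5752740	del/dupl	OR2T5	25 breeds
52	14	5305030	5752740	del/dupl	OR2T6	25 breeds
69	19	13816712	15228649	dupl	PHF17	Chinese Shar-Pei
106	36	24468560	24970441	dupl	OSBPL6	Brittany Spaniel,English Setter
106	36	24468560	24970441	dupl	PDE11A	Brittany Spaniel,English Setter
106	36	24468560	24970441	dupl	RBM45	Brittany Spaniel,English Setter
108	37	31546053	31684318	dupl	SGPP2	Chinese Shar-Pei,Eurasian
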