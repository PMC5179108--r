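family	section	gene	hgvs_c	hgvs_p	consequence	zygosity	role	cosegregation	reported	pp2_call	pp2_score	sift_call	sift_score	mt_call	mt_score	cadd	exac_ac	exac_an	exac_status	printed_class
A10	A	C21orf2	c.286G>A	p.E96K	missense	het	causal	consistent	novel	Probably D.	1	Tolerated	NA	Disease C.	1	36	NA	NA	absent	LikelyPathogenic
A10	A	C21orf2	c.631_632del	p.R211Hfs*46	frameshift	het	causal	consistent	novel	NA	NA	NA	NA	Disease C.	1	NA	NA	NA	absent	Pathogenic
64ORG	A	PHYH	c.668C>G	p.P223R	missense	het	causal	consistent	novel	Probably D.	1	Tolerated	0.06	Disease C.	1	22.7	NA	NA	absent	LikelyPathogenic
64ORG	A	PHYH	c.683dupG	p.V229Sfs*2	frameshift	het	causal	consistent	reported_pathogenic	NA	NA	NA	NA	Disease C.	1	NA	2	121412	observed	Pathogenic
79ORG	A	USH2A	c.2299delG	p.E767Sfs*21	frameshift	het	causal	consistent	reported_pathogenic	NA	NA	NA	NA	NA	NA	NA	96	121284	observed	Pathogenic
79ORG	A	USH2A	c.9119G>A	p.W3040*	nonsense	het	causal	consistent	reported_pathogenic	NA	NA	Tolerated	1	Disease C.	1	52	NA	NA	absent	Pathogenic
77ORG	B	ABCA4	c.3386G>T	p.R1129L	missense	het	causal	consistent	reported_pathogenic	Probably D.	0.961	Damaging	0	Disease C.	1	28.01	30	121388	observed	LikelyPathogenic
77ORG	B	ABCA4	c.4539+2064C>T	NA	deep_intronic	het	causal	consistent	reported_pathogenic	NA	NA	NA	NA	Polymorphism	0	NA	NA	NA	not_covered	VUS
A18	B	BBS2	c.334T>C	p.F112L	missense	hom_alt	causal	consistent	novel	Probably D.	1	Damaging	0.01	Disease C.	1	28.8	1	121022	observed	VUS
55ORG	B	C2orf71	c.1067_1068del	p.N356Rfs*101	frameshift	hom_alt	causal	unavailable	novel	NA	NA	NA	NA	Disease C.	1	NA	NA	NA	absent	Pathogenic
65ORG	B	CEP290	c.148C>T	p.H50Y	missense	het	causal	unavailable	novel	Possibly D.	0.952	Damaging	0.05	Disease C.	1	25	NA	NA	absent	VUS
65ORG	B	CEP290	c.1322T>A	p.L441*	nonsense	het	causal	unavailable	novel	NA	NA	Tolerated	1	Disease C.	1	41	NA	NA	absent	Pathogenic
67ORG	B	CERKL	c.613+5_613+8del	NA	noncanonical_splice_region	hom_alt	causal	consistent	novel	NA	NA	NA	NA	Disease C.	1	NA	NA	NA	absent	VUS
75ORG	B	CNGA3	c.1768G>A	p.E590K	missense	hom_alt	causal	consistent	reported_pathogenic	Probably D.	0.954	Damaging	0.05	Disease C.	1	22.8	1	121004	observed	VUS
80ORG	B	CNGB1	c.2762_2765delACGA	p.Y921Cfs*15	frameshift	hom_alt	causal	consistent	novel	NA	NA	NA	NA	NA	NA	NA	NA	NA	absent	Pathogenic
71ORG	B	CNGB3	c.1148delC	p.T383Ifs*13	frameshift	hom_alt	causal	consistent	reported_pathogenic	NA	NA	NA	NA	Disease C.	1	NA	224	120952	observed	Pathogenic
2ORG	B	CRB1	c.2688T>A	p.C896*	nonsense	het	causal	unavailable	reported_pathogenic	NA	NA	Tolerated	1	Disease C.	1	23.2	2	121386	observed	Pathogenic
2ORG	B	CRB1	c.2842T>C	p.C948R	missense	het	causal	unavailable	novel	Probably D.	0.996	Damaging	0	Disease C.	1	15.2	NA	NA	absent	LikelyPathogenic
10NCE	B	CRX	deletion_exons_3-4	NA	exonic_deletion	het	causal	consistent	novel	NA	NA	NA	NA	NA	NA	NA	NA	NA	absent	Pathogenic
68ORG	B	EYS	c.2380C>T	p.R794*	nonsense	het	causal	consistent	novel	NA	NA	NA	NA	Disease C.	1	37	1	19764	observed	Pathogenic
68ORG	B	EYS	deletion_10_initial_exons	NA	exonic_deletion	het	causal	consistent	novel	NA	NA	NA	NA	NA	NA	NA	NA	NA	absent	Pathogenic
58ORG	B	GUCY2D	c.914delA	p.H305Pfs*90	frameshift	hom_alt	causal	consistent	novel	NA	NA	NA	NA	Disease C.	1	NA	NA	NA	absent	Pathogenic
69ORG	B	NRL	c.339C>G	p.Y113*	nonsense	hom_alt	causal	consistent	novel	NA	NA	NA	NA	Disease C.	1	37	NA	NA	absent	Pathogenic
81ORG	B	OPA1	c.800_801delAA	p.K267Rfs*4	frameshift	het	causal	consistent	novel	NA	NA	NA	NA	NA	NA	NA	1	120600	observed	Pathogenic
E4	B	PRPF31	deletion_exons_1-13_duplication_exons_2-5	NA	exonic_deletion	het	causal	consistent	novel	NA	NA	NA	NA	NA	NA	NA	NA	NA	absent	Pathogenic
76ORG	B	RPGR	c.762_777delinsCA	p.T255Rfs*23	frameshift	hemizygous	causal	consistent	novel	NA	NA	NA	NA	NA	NA	NA	NA	NA	absent	Pathogenic
82ORG	B	UNC119	c.7delG	p.V3*	frameshift	het	causal	unavailable	novel	NA	NA	NA	NA	NA	NA	NA	NA	NA	absent	LikelyPathogenic
51ORG	B	USH2A	c.1724G>A	p.C575Y	missense	het	causal	consistent	reported_pathogenic	Probably D.	1	Damaging	0	Disease C.	1	16.57	1	121370	observed	LikelyPathogenic
51ORG	B	USH2A	c.2276G>T	p.C759F	missense	het	causal	consistent	reported_pathogenic	Probably D.	0.999	Damaging	0	Disease C.	1	23.1	95	121178	observed	LikelyPathogenic
73ORG	B	USH2A	c.2276G>T	p.C759F	missense	het	causal	consistent	reported_pathogenic	Probably D.	0.999	Damaging	0	Disease C.	1	23.1	95	121178	observed	LikelyPathogenic
73ORG	B	USH2A	c.13010C>T	p.T4337M	missense	het	causal	consistent	reported_pathogenic	Probably D.	0.986	Damaging	0	Disease C.	1	24.8	NA	NA	absent	LikelyPathogenic
22ORG	C	CNGB3	c.1672G>T	p.G558C	missense	het	causal	inconsistent	reported_pathogenic	Probably D.	1	Damaging	0	Disease C.	1	26.8	4	119080	observed	VUS
22ORG	C	CRB1	c.1702C>T	p.H568Y	missense	het	modifier	consistent	reported_pathogenic	Probably D.	0.997	Tolerated	1	Disease C.	1	16.43	NA	NA	absent	VUS
22ORG	C	ROM1	c.668G>A	p.R223Q	missense	het	modifier	consistent	novel	Probably D.	0.999	Tolerated	0.09	Disease C.	1	36	17	121408	observed	VUS
39ORG	C	PDE6B	c.928-9_940dup	p.Y314Cfs*50	frameshift	het	causal	inconsistent	reported_pathogenic	NA	NA	NA	NA	NA	NA	NA	NA	NA	absent	Pathogenic
39ORG	C	USH2A	c.1246G>T	p.A416S	missense	het	modifier	consistent	novel	Probably D.	0.998	Tolerated	0.1	Disease C.	1	24.5	1	117386	observed	VUS
A3	D	CEP250	c.1826C>T	p.A609V	missense	hom_alt	causal	consistent	novel	Probably D.	NA	Damaging	NA	Neutral	NA	20.6	33	121314	observed	LikelyPathogenic
56ORG	D	CEP78	c.1056delT	p.T353Lfs*5	frameshift	hom_alt	causal	consistent	novel	NA	NA	NA	NA	Disease C.	1	NA	NA	NA	absent	VGUS
62ORG	D	SCLT1	c.778-2A>T	NA	canonical_splice	het	causal	consistent	novel	NA	NA	NA	NA	Disease C.	1	19.45	NA	NA	absent	Pathogenic
62ORG	D	SCLT1	c.827G>A	p.R276H	missense	het	causal	consistent	novel	Probably D.	0.998	NA	NA	Disease C.	1	20.6	3	121324	observed	VUS
66ORG	D	SEMA6B	c.493G>A	p.G165R	missense	hom_alt	causal	consistent	novel	Possibly D.	0.814	Damaging	0.03	Disease C.	0.995	14.13	1	118664	observed	VGUS
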