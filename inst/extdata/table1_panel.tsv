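gene	association	modes	lof_mechanism	functional_support
C21orf2	established_syndromic	AR	TRUE	FALSE
PHYH	established_syndromic	AR	TRUE	FALSE
USH2A	established_IRD	AR	TRUE	FALSE
ABCA4	established_IRD	AR	TRUE	FALSE
BBS2	established_syndromic	AR	TRUE	FALSE
C2orf71	established_IRD	AR	TRUE	FALSE
CEP290	established_IRD	AR	TRUE	FALSE
CERKL	established_IRD	AR	TRUE	FALSE
CNGA3	established_IRD	AR	TRUE	FALSE
CNGB1	established_IRD	AR	TRUE	FALSE
CNGB3	established_IRD	AR,AD	TRUE	FALSE
CRB1	established_IRD	AR	TRUE	FALSE
CRX	established_IRD	AD	TRUE	FALSE
EYS	established_IRD	AR	TRUE	FALSE
GUCY2D	established_IRD	AR	TRUE	FALSE
NRL	established_IRD	AR,AD	TRUE	FALSE
OPA1	established_IRD	AD	TRUE	FALSE
PDE6B	established_IRD	AR,AD	TRUE	FALSE
PRPF31	established_IRD	AD	TRUE	FALSE
ROM1	established_IRD	AD	TRUE	FALSE
RPGR	established_IRD	XL	TRUE	FALSE
UNC119	established_IRD	AD	TRUE	FALSE
CEP250	candidate_gene	AR	TRUE	TRUE
CEP78	candidate_gene	AR	TRUE	FALSE
SCLT1	candidate_gene	AR	TRUE	FALSE
SEMA6B	candidate_gene	AR	TRUE	FALSE
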