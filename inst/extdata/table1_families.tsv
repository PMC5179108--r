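family	section	disease	model	secure_diagnosis	synthetic
A10	A	ar axial SMD	AR_comphet	TRUE	FALSE
64ORG	A	ar Refsum	AR_comphet	TRUE	FALSE
79ORG	A	arUSH	AR_comphet	TRUE	FALSE
77ORG	B	arCD	AR_comphet	FALSE	FALSE
A18	B	arRP	AR_hom	FALSE	FALSE
55ORG	B	arCRD	AR_hom	TRUE	FALSE
65ORG	B	arLCA	AR_comphet	FALSE	FALSE
67ORG	B	arRP	AR_hom	FALSE	FALSE
75ORG	B	arAchr	AR_hom	FALSE	FALSE
80ORG	B	arRP	AR_hom	TRUE	FALSE
71ORG	B	arAchr	AR_hom	TRUE	FALSE
2ORG	B	arRP	AR_comphet	TRUE	FALSE
10NCE	B	adRP	AD	TRUE	FALSE
68ORG	B	arRP	AR_comphet	TRUE	FALSE
58ORG	B	arLCA	AR_hom	TRUE	FALSE
69ORG	B	arGF	AR_hom	TRUE	FALSE
81ORG	B	adOA	AD	TRUE	FALSE
E4	B	adRP	AD	TRUE	FALSE
76ORG	B	XlRP	XL	TRUE	FALSE
82ORG	B	adRP	AD	TRUE	FALSE
51ORG	B	arRP	AR_comphet	TRUE	FALSE
73ORG	B	arRP	AR_comphet	TRUE	FALSE
22ORG	C	RP	AD	FALSE	FALSE
39ORG	C	RP	AD	FALSE	FALSE
A3	D	arRP	AR_hom	TRUE	FALSE
56ORG	D	arRP	AR_hom	FALSE	FALSE
62ORG	D	arRP	AR_comphet	FALSE	FALSE
66ORG	D	arCRD	AR_hom	FALSE	FALSE
UNSOLVED1	none	IRD	none	FALSE	TRUE
UNSOLVED2	none	IRD	none	FALSE	TRUE
UNSOLVED3	none	IRD	none	FALSE	TRUE
UNSOLVED4	none	IRD	none	FALSE	TRUE
UNSOLVED5	none	IRD	none	FALSE	TRUE
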