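variable	level	dhgp	rhgp
gender	male	14	11
gender	female	6	4
location	left_rectum	14	10
location	right	6	5
pt_stage	T1-2	1	2
pt_stage	T3	17	12
pt_stage	T4	2	1
pn_stage	N0	12	5
pn_stage	N1	7	6
pn_stage	N2	1	4
extrahepatic	yes	5	2
extrahepatic	no	15	13
preop_chemo	yes	18	13
preop_chemo	no	2	2
hepatitis_b	yes	3	0
hepatitis_b	no	17	15
smoking	yes	1	3
smoking	no	19	12
hypertension	yes	4	1
hypertension	no	16	14
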