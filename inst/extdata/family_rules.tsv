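family	kind	pattern	amidation_required	priority
luqin	c_terminal	WRPQGRF	TRUE	1
npf	c_terminal	GRPRF	TRUE	2
cck_sk	c_terminal	GGGRF	TRUE	3
fxriamide	c_terminal	xSSFxRI	TRUE	4
myomodulin	c_terminal	xxxMLRL	TRUE	5
apgwamide	full_pattern	[ARTK]PGW	TRUE	6
allatostatin_b	trp_spacing	4|5	TRUE	7
allatostatin_c	cys_spacing	6	TRUE	8
gxlamide	c_terminal	GxL	TRUE	9
ryamide	c_terminal	RY	TRUE	10
rfamide	c_terminal	RF	TRUE	11
wamide	c_terminal	W	TRUE	12
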