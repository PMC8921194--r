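symbol	tier	cmp_class	category	inheritance	pli	heart_expression
NRAP	candidate	candidate	other	AD	0.96	high
FHOD3	candidate	candidate	other	AD	0.98	high
MYOM1	candidate	candidate	other	AD	0.45	high
SYNPO2L	candidate	candidate	other	AD	0.91	moderate
KLHL31	candidate	candidate	other	AD	0.72	moderate
TRIM55	candidate	candidate	other	AD	0.31	high
XIRP2	candidate	candidate	other	AD	0.94	high
CMYA5	candidate	candidate	other	AD	0.12	moderate
LRRC10	candidate	candidate	other	AD	0.93	high
SORBS2	candidate	candidate	other	AD	0.55	moderate
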