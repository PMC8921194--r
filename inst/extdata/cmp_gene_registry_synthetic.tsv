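symbol	tier	cmp_class	category	inheritance	pli	heart_expression
MYH7	1	primary	sarcomere	AD	0.962	high
MYBPC3	1	primary	sarcomere	AD	0.995	high
TNNT2	1	primary	sarcomere	AD	0.285	high
TNNI3	1	primary	sarcomere	AD	0.668	high
TPM1	1	primary	sarcomere	AD	0.404	high
ACTC1	1	primary	sarcomere	AD	0.331	high
MYL2	1	primary	sarcomere	AD	0.38	high
MYL3	1	primary	sarcomere	AD	0.467	high
ACTN2	1	primary	sarcomere	AD	0.37	high
DSP	1	primary	desmosomal	AD	0.965	high
DSC2	1	primary	desmosomal	AD	0.075	low
DSG2	1	primary	desmosomal	AD	0.561	moderate
PKP2	1	primary	desmosomal	AD	0.134	high
JUP	1	primary	desmosomal	AD	0.27	moderate
CTNNA3	2	primary	desmosomal	AD	0.925	low
TMEM43	1	primary	desmosomal	AD	0.805	high
DES	1	primary	cytoskeletal	AD	0.352	high
FLNC	1	primary	cytoskeletal	AD	0.951	high
VCL	1	primary	cytoskeletal	AD	0.978	moderate
NEXN	1	primary	cytoskeletal	AD	0.964	moderate
LDB3	1	primary	cytoskeletal	AD	0.671	low
CSRP3	1	primary	cytoskeletal	AD	0.456	moderate
TCAP	1	primary	cytoskeletal	AD	0.447	high
ANKRD1	2	primary	cytoskeletal	AD	0.786	high
MYPN	1	primary	cytoskeletal	AD	0.481	moderate
CRYAB	1	primary	cytoskeletal	AD	0.472	high
BAG3	1	primary	cytoskeletal	AD	0.987	high
MYOZ2	2	primary	cytoskeletal	AD	0.252	high
NEBL	2	primary	cytoskeletal	AD	0.78	moderate
DMD	1	secondary	cytoskeletal	XL	0.974	moderate
SGCD	1	primary	cytoskeletal	AD	0.927	moderate
ILK	2	primary	cytoskeletal	AD	0.034	high
PDLIM3	2	primary	cytoskeletal	AD	0.059	low
TTN	1	primary	cytoskeletal	AD	0.972	high
OBSCN	2	primary	cytoskeletal	AD	0.522	moderate
SPEG	2	primary	cytoskeletal	AD	0.709	high
TRIM63	2	primary	cytoskeletal	AD	0.686	moderate
MURC	2	primary	cytoskeletal	AD	0.791	moderate
LAMA4	1	primary	cytoskeletal	AD	0.262	high
FKTN	1	secondary	dystroglycan	AR	0.476	high
DTNA	1	primary	dystroglycan	AD	0.107	low
FKRP	1	secondary	dystroglycan	AR	0.862	high
LARGE1	1	primary	dystroglycan	AR	0.34	moderate
POMT1	1	secondary	dystroglycan	AR	0.727	high
POMT2	1	secondary	dystroglycan	AR	0.988	high
POMGNT1	2	secondary	dystroglycan	AR	0.348	high
DAG1	2	primary	dystroglycan	AR	0.959	high
RYR2	2	primary	ion_channel	AD	0.99	high
SCN5A	1	primary	ion_channel	AD	0.983	moderate
KCNQ1	1	primary	ion_channel	AD	0.714	high
KCNJ2	2	primary	ion_channel	AD	0.85	moderate
HCN4	2	primary	ion_channel	AD	0.61	low
ABCC9	1	primary	ion_channel	AD	0.971	high
CACNA1C	2	primary	ion_channel	AD	0.602	high
PLN	1	primary	ion_channel	AD	0.141	high
CASQ2	1	primary	ion_channel	AR	0.819	high
CAV3	1	primary	ion_channel	AD	0.386	moderate
LMNA	1	primary	other	AD	0.998	high
EMD	1	secondary	other	XL	0.862	high
FHL1	1	secondary	other	XL	0.106	moderate
FHL2	1	primary	other	AD	0.673	high
LAMP2	1	secondary	other	XL	0.475	high
GLA	1	secondary	other	XL	0.585	high
PRKAG2	1	primary	other	AD	0.583	high
RBM20	1	primary	other	AD	0.971	moderate
TAZ	1	secondary	other	XL	0.732	moderate
EYA4	2	primary	other	AD	0.705	high
GATAD1	2	primary	other	AD	0.453	moderate
MIB1	2	primary	other	AD	0.962	high
PRDM16	1	primary	other	AD	0.303	high
ALPK3	1	primary	other	AD	0.538	high
CALR3	2	primary	other	AD	0.215	moderate
MYLK2	2	primary	other	AD	0.57	high
TTR	2	secondary	other	AD	0.683	moderate
TGFB3	1	primary	other	AD	0.855	high
JPH2	1	primary	other	AD	0.985	high
PSEN1	1	secondary	other	AD	0.216	moderate
PSEN2	1	secondary	other	AD	0.496	high
SDHA	1	secondary	other	AR	0.063	moderate
TBX20	1	primary	other	AD	0.091	high
GATA4	1	primary	other	AD	0.415	moderate
NKX2-5	1	primary	other	AD	0.029	moderate
DNAJC19	1	secondary	other	AR	0.299	high
DOLK	1	secondary	other	AR	0.548	high
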