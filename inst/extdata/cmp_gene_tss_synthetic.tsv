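gene	chrom	position	strand
MYH7	chr1	1000461	-
MYBPC3	chr2	1505962	-
TNNT2	chr3	2006202	+
TNNI3	chr4	2503617	-
TPM1	chr5	3000111	-
ACTC1	chr6	3503967	-
MYL2	chr7	4002873	-
MYL3	chr8	4502144	-
ACTN2	chr9	5005374	-
DSP	chr10	5509493	+
DSC2	chr11	6005851	-
DSG2	chr12	6505494	+
PKP2	chr13	7007863	-
JUP	chr14	7502683	-
CTNNA3	chr15	8002094	-
TMEM43	chr16	8508579	+
DES	chr17	9006053	-
FLNC	chr18	9501171	-
VCL	chr19	10008494	+
NEXN	chr20	10500273	+
LDB3	chr21	11000933	-
CSRP3	chr22	11504318	+
TCAP	chr1	12005749	+
ANKRD1	chr2	12505855	+
MYPN	chr3	13006969	+
CRYAB	chr4	13507238	+
BAG3	chr5	14009692	-
MYOZ2	chr6	14509879	-
NEBL	chr7	15001194	-
DMD	chrX	15503948	+
SGCD	chr8	16005231	+
ILK	chr9	16500283	-
PDLIM3	chr10	17006936	+
TTN	chr11	17502415	-
OBSCN	chr12	18008518	+
SPEG	chr13	18509808	-
TRIM63	chr14	19006187	+
MURC	chr15	19508964	+
LAMA4	chr16	20002051	-
FKTN	chr17	20500064	+
DTNA	chr18	21004827	+
FKRP	chr19	21504344	+
LARGE1	chr20	22006692	+
POMT1	chr21	22505207	+
POMT2	chr22	23009088	-
POMGNT1	chr1	23509909	+
DAG1	chr2	24009866	-
RYR2	chr3	24506759	-
SCN5A	chr4	25003282	+
KCNQ1	chr5	25502517	+
KCNJ2	chr6	26005473	-
HCN4	chr7	26508134	-
ABCC9	chr8	27001719	+
CACNA1C	chr9	27505728	+
PLN	chr10	28000737	+
CASQ2	chr11	28507449	-
CAV3	chr12	29009689	-
LMNA	chr13	29505761	-
EMD	chrX	30002027	-
FHL1	chrX	30504126	+
FHL2	chr14	31002445	+
LAMP2	chrX	31508277	-
GLA	chrX	32009428	-
PRKAG2	chr15	32501723	+
RBM20	chr16	33008414	-
TAZ	chrX	33509923	-
EYA4	chr17	34008151	-
GATAD1	chr18	34505703	+
MIB1	chr19	35008045	+
PRDM16	chr20	35504320	+
ALPK3	chr21	36005584	+
CALR3	chr22	36502401	+
MYLK2	chr1	37005801	-
TTR	chr2	37502299	-
TGFB3	chr3	38001610	-
JPH2	chr4	38502678	+
PSEN1	chr5	39008700	-
PSEN2	chr6	39501558	+
SDHA	chr7	40008010	-
TBX20	chr8	40509335	+
GATA4	chr9	41004098	-
NKX2-5	chr10	41506369	+
DNAJC19	chr11	42001518	+
DOLK	chr12	42502502	+
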