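aa3	aa1	hydropathy	polarity	sidechain_volume	pI	mass	charge
ALA	A	1.8	8.1	88.6	6.00	71.08	0
ARG	R	-4.5	10.5	173.4	10.76	156.19	1
ASN	N	-3.5	11.6	114.1	5.41	114.10	0
ASP	D	-3.5	13.0	111.1	2.77	115.09	-1
CYS	C	2.5	5.5	108.5	5.07	103.14	0
GLN	Q	-3.5	10.5	143.8	5.65	128.13	0
GLU	E	-3.5	12.3	138.4	3.22	129.12	-1
GLY	G	-0.4	9.0	60.1	5.97	57.05	0
HIS	H	-3.2	10.4	153.2	7.59	137.14	0
ILE	I	4.5	5.2	166.7	6.02	113.16	0
LEU	L	3.8	4.9	166.7	5.98	113.16	0
LYS	K	-3.9	11.3	168.6	9.74	128.17	1
MET	M	1.9	5.7	162.9	5.74	131.19	0
PHE	F	2.8	5.2	189.9	5.48	147.18	0
PRO	P	-1.6	8.0	112.7	6.30	97.12	0
SER	S	-0.8	9.2	89.0	5.68	87.08	0
THR	T	-0.7	8.6	116.1	5.60	101.10	0
TRP	W	-0.9	5.4	227.8	5.89	186.21	0
TYR	Y	-1.3	6.2	193.6	5.66	163.18	0
VAL	V	4.2	5.9	140.0	5.96	99.13	0
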