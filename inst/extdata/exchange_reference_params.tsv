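# Side-chain nearest-neighbour factors for intrinsic backbone-amide
# hydrogen-exchange rates (poly-DL-alanine reference, D2O, log10 units).
# "L" applies to the residue's own amide, "R" to the amide of the following
# residue.  Titratable side chains carry charged/neutral variants mixed by
# the listed pKa (D2O scale) at the working pD.
code	variant	acidL	acidR	baseL	baseR	pKa
ALA	std	0.00	0.00	0.00	0.00	NA
ARG	std	-0.59	-0.32	0.08	0.22	NA
ASN	std	-0.58	-0.13	0.49	0.32	NA
ASP	charged	0.90	0.58	-0.30	-0.18	4.48
ASP	neutral	-0.90	-0.12	0.69	0.60	4.48
CYS	std	-0.54	-0.46	0.62	0.55	NA
CYX	std	-0.74	-0.58	0.55	0.46	NA
GLY	std	-0.22	0.22	0.27	0.17	NA
GLN	std	-0.47	-0.27	0.06	0.20	NA
GLU	charged	-0.90	0.31	-0.51	-0.15	4.93
GLU	neutral	-0.60	-0.27	0.24	0.39	4.93
HIS	charged	-0.80	-0.51	0.80	0.83	7.00
HIS	neutral	0.00	0.00	-0.10	0.14	7.00
ILE	std	-0.91	-0.59	-0.73	-0.23	NA
LEU	std	-0.57	-0.13	-0.58	-0.21	NA
LYS	std	-0.56	-0.29	-0.04	0.12	NA
MET	std	-0.64	-0.28	-0.01	0.11	NA
PHE	std	-0.52	-0.43	-0.24	0.06	NA
PRO	std	0.00	-0.19	0.00	-0.24	NA
SER	std	-0.44	-0.39	0.37	0.30	NA
THR	std	-0.79	-0.47	-0.07	0.20	NA
TRP	std	-0.40	-0.44	-0.41	-0.11	NA
TYR	std	-0.41	-0.37	-0.27	0.05	NA
VAL	std	-0.74	-0.30	-0.70	-0.14	NA
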