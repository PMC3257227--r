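# Reference residue-resolved H/D exchange results for monomeric BS-RNase
# (mBS) at pH 5.65-5.7, 300 K: observed exchange rate k_obs (1/hr) with
# least-squares error, protection factor P, and opening free energy
# dG_op (kcal/mol) with error.  Used by the regression tests for the
# thermodynamic consistency dG_op = RT ln(P).
residue	seq	k_obs	k_obs_err	P	dG_op	dG_op_err
PHE	8	0.114	0.046	8.87e3	5.40	0.04
GLU	9	0.273	0.015	1.82e3	4.46	0.02
ARG	10	0.130	0.018	9.03e3	5.41	0.06
GLN	11	0.026	0.015	9.75e4	6.82	0.04
HIS	12	0.038	0.016	2.48e5	7.38	0.06
ASP	14	0.190	0.027	4.83e3	5.04	0.01
SER	21	0.040	0.100	1.56e5	7.01	0.03
CYS	26	0.109	0.057	4.86e4	6.41	0.02
LEU	28	0.640	0.073	1.15e3	4.18	0.02
MET	30	0.011	0.016	1.53e5	7.09	0.02
CYS	31	0.134	0.019	4.54e4	6.37	0.01
CYS	32	2.220	0.570	6.13e3	5.18	0.02
ARG	33	0.249	0.028	1.85e4	5.84	0.01
LYS	34	0.262	0.017	7.70e3	5.32	0.05
LYS	41	0.200	0.084	1.75e4	5.80	0.04
VAL	43	0.469	0.101	3.39e2	3.46	0.06
ASN	44	0.031	0.010	9.62e4	6.81	0.09
GLU	49	0.044	0.015	6.78e4	6.61	0.01
ASP	53	0.725	0.120	9.90e2	4.10	0.03
ALA	56	0.059	0.006	2.96e4	6.12	0.02
VAL	57	0.003	0.007	7.90e4	6.70	0.04
CYS	58	0.010	0.006	3.39e5	7.56	0.01
SER	59	0.425	0.052	2.12e4	5.91	0.01
LYS	61	0.062	0.075	3.11e4	6.14	0.02
GLN	69	0.026	0.072	8.70e4	6.76	0.04
GLN	74	0.005	0.014	3.43e5	7.57	0.05
SER	77	0.011	0.044	3.73e5	7.62	0.03
ARG	80	0.191	0.026	1.08e4	5.52	0.02
ILE	81	0.007	0.015	5.91e4	6.53	0.06
THR	82	0.005	0.021	1.34e5	7.01	0.05
ASP	83	0.182	0.025	6.19e3	5.19	0.03
CYS	84	0.027	0.017	1.21e5	6.95	0.04
ARG	85	0.016	0.015	2.88e5	7.47	0.01
GLU	86	0.083	0.016	8.63e3	5.38	0.09
SER	89	0.033	0.025	1.40e5	7.04	0.03
LYS	91	0.038	0.013	6.38e4	6.57	0.10
ALA	96	0.621	0.112	6.21e3	5.19	0.08
TYR	97	0.252	0.034	2.84e3	4.73	0.02
THR	100	0.057	0.015	3.15e4	6.15	0.06
VAL	102	0.023	0.010	1.85e4	5.83	0.02
LYS	104	0.014	0.079	5.44e4	6.48	0.04
ILE	106	0.008	0.013	1.61e5	7.12	0.02
ALA	109	0.014	0.014	6.89e4	6.62	0.07
GLY	111	0.322	0.086	2.21e4	5.94	0.06
VAL	118	0.012	0.022	1.30e4	5.63	0.02
HIS	119	0.026	0.012	1.66e5	7.14	0.05
VAL	124	0.360	0.038	3.26e1	2.07	0.04
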