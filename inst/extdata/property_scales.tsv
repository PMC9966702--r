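residue	hydrophobicity	hydrophilicity	polarity	charge	polarizability	volume	helix_propensity	max_sasa
A	1.8	-0.5	8.1	0	0.046	88.6	1.42	129
R	-4.5	3.0	10.5	1	0.291	173.4	0.98	274
N	-3.5	0.2	11.6	0	0.134	114.1	0.67	195
D	-3.5	3.0	13.0	-1	0.105	111.1	1.01	193
C	2.5	-1.0	5.5	0	0.128	108.5	0.70	167
Q	-3.5	0.2	10.5	0	0.180	143.8	1.11	225
E	-3.5	3.0	12.3	-1	0.151	138.4	1.51	223
G	-0.4	0.0	9.0	0	0.000	60.1	0.57	104
H	-3.2	-0.5	10.4	0	0.230	153.2	1.00	224
I	4.5	-1.8	5.2	0	0.186	166.7	1.08	197
L	3.8	-1.8	4.9	0	0.186	166.7	1.21	201
K	-3.9	3.0	11.3	1	0.219	168.6	1.16	236
M	1.9	-1.3	5.7	0	0.221	162.9	1.45	224
F	2.8	-2.5	5.2	0	0.290	189.9	1.13	240
P	-1.6	0.0	8.0	0	0.131	112.7	0.57	159
S	-0.8	0.3	9.2	0	0.062	89.0	0.77	155
T	-0.7	-0.4	8.6	0	0.108	116.1	0.83	172
W	-0.9	-3.4	5.4	0	0.409	227.8	1.08	285
Y	-1.3	-2.3	6.2	0	0.298	193.6	0.69	263
V	4.2	-1.5	5.9	0	0.140	140.0	1.06	174
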