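residue	hydrophobicity	hydrophilicity	bulkiness	net_hydrogen	steric_hindrance	amphipathicity	charge	pI	side_chain_volume	polarity
A	1.8	-0.5	11.50	0	0.52	0.00	0.0	6.00	88.6	8.1
C	2.5	-1.0	13.46	1	0.62	0.00	0.0	5.07	108.5	5.5
D	-3.5	3.0	11.68	1	0.76	0.00	-1.0	2.77	111.1	13.0
E	-3.5	3.0	13.57	1	0.68	1.27	-1.0	3.22	138.4	12.3
F	2.8	-2.5	19.80	0	0.70	0.00	0.0	5.48	189.9	5.2
G	-0.4	0.0	3.40	0	0.00	0.00	0.0	5.97	60.1	9.0
H	-3.2	-0.5	13.69	1	0.70	1.45	0.1	7.59	153.2	10.4
I	4.5	-1.8	21.40	0	1.02	0.00	0.0	6.02	166.7	5.2
K	-3.9	3.0	15.71	3	0.68	3.67	1.0	9.74	168.6	11.3
L	3.8	-1.8	21.40	0	0.98	0.00	0.0	5.98	166.7	4.9
M	1.9	-1.3	16.25	0	0.78	0.00	0.0	5.74	162.9	5.7
N	-3.5	0.2	12.82	2	0.76	0.00	0.0	5.41	114.1	11.6
P	-1.6	0.0	17.43	0	0.36	0.00	0.0	6.30	112.7	8.0
Q	-3.5	0.2	14.45	2	0.68	1.25	0.0	5.65	143.8	10.5
R	-4.5	3.0	14.28	5	0.68	2.45	1.0	10.76	173.4	10.5
S	-0.8	0.3	9.47	1	0.53	0.00	0.0	5.68	89.0	9.2
T	-0.7	-0.4	15.77	1	0.50	0.00	0.0	5.60	116.1	8.6
V	4.2	-1.5	21.57	0	0.76	0.00	0.0	5.96	140.0	5.9
W	-0.9	-3.4	21.67	1	0.70	6.93	0.0	5.89	227.8	5.4
Y	-1.3	-2.3	18.03	1	0.70	5.06	0.0	5.66	193.6	6.2
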