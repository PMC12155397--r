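type	element	default	r1	theta0	x1	D1	zeta	Z1	Vi	Uj	Xi
H_	H	1	0.354	180.00	2.886	0.044	12.000	0.712	0.000	0.000	4.528
He4+4	He	1	0.849	90.00	2.362	0.056	15.240	0.098	0.000	0.000	9.660
C_3	C	1	0.757	109.47	3.851	0.105	12.730	1.912	2.119	2.000	5.343
C_R	C	0	0.729	120.00	3.851	0.105	12.730	1.912	0.000	2.000	5.343
C_2	C	0	0.732	120.00	3.851	0.105	12.730	1.912	0.000	2.000	5.343
C_1	C	0	0.706	180.00	3.851	0.105	12.730	1.912	0.000	2.000	5.343
N_3	N	1	0.700	106.70	3.660	0.069	13.407	2.544	0.450	2.000	6.899
N_R	N	0	0.699	120.00	3.660	0.069	13.407	2.544	0.000	2.000	6.899
N_2	N	0	0.685	111.20	3.660	0.069	13.407	2.544	0.000	2.000	6.899
N_1	N	0	0.656	180.00	3.660	0.069	13.407	2.544	0.000	2.000	6.899
O_3	O	1	0.658	104.51	3.500	0.060	14.085	2.300	0.018	2.000	8.741
O_R	O	0	0.680	110.00	3.500	0.060	14.085	2.300	0.000	2.000	8.741
O_2	O	0	0.634	120.00	3.500	0.060	14.085	2.300	0.000	2.000	8.741
O_1	O	0	0.639	180.00	3.500	0.060	14.085	2.300	0.000	2.000	8.741
F_	F	1	0.668	180.00	3.364	0.050	14.762	1.735	0.000	2.000	10.874
Ne4+4	Ne	1	0.920	90.00	3.243	0.042	15.440	0.194	0.000	2.000	11.043
Na	Na	1	1.539	180.00	2.983	0.030	12.000	1.081	0.000	1.250	2.843
Mg3+2	Mg	1	1.421	109.47	3.021	0.111	12.000	1.787	0.000	1.250	3.951
P_3+3	P	1	1.101	93.80	4.147	0.305	13.072	2.863	2.400	1.250	5.463
S_3+2	S	1	1.064	92.10	4.035	0.274	13.969	2.703	0.484	1.250	6.928
S_R	S	0	1.096	92.20	4.035	0.274	13.969	2.703	0.000	1.250	6.928
S_2	S	0	0.854	120.00	4.035	0.274	13.969	2.703	0.000	1.250	6.928
Cl	Cl	1	1.044	180.00	3.947	0.227	14.866	2.348	0.000	1.250	8.564
Ar4+4	Ar	1	1.032	90.00	3.868	0.185	15.763	0.300	0.000	1.250	9.465
K_	K	1	1.953	180.00	3.812	0.035	12.000	1.165	0.000	0.700	2.421
Ca6+2	Ca	1	1.761	90.00	3.399	0.238	12.000	2.141	0.000	0.700	3.231
Fe3+2	Fe	1	1.270	109.47	4.540	0.013	12.000	2.110	0.000	0.700	3.760
Fe6+2	Fe	0	1.335	90.00	4.540	0.013	12.000	2.110	0.000	0.700	3.760
Zn3+2	Zn	1	1.193	109.47	4.045	0.124	12.000	1.308	0.000	0.700	5.106
Br	Br	1	1.192	180.00	4.189	0.251	15.000	2.519	0.000	0.700	7.790
I_	I	1	1.382	180.00	4.500	0.339	15.000	2.650	0.000	0.200	6.822
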