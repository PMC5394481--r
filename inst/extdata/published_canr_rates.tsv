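background	mmr	allele	rate	ci_low	ci_high	p_display	effect
POL3	MSH2	control	2.2	1.3	3.4	NA	NA
POL3	MSH2	S319F	7.4	4.8	11	0.001	3.3
POL3	MSH2	G447D	1.8	0.9	3.1	ns	0.8
POL3	MSH2	F467I	6.5	3.9	10	0.018	2.9
POL3	MSH2	K559N	8.5	4.3	15	0.014	3.8
POL3	MSH2	S611Y	2.8	0.9	6.5	ns	1.3
POL3	MSH2	R658G	5.5	3.0	9.2	ns	2.5
POL3	MSH2	A704V	4.9	1.9	9.8	ns	2.2
POL3	MSH2	G818C	7.2	2.9	15	ns	3.2
POL3	msh2	control	70	45	99	NA	NA
POL3	msh2	S319F	490	390	600	<0.0001	7.1
POL3	msh2	G447D	76	59	94	ns	1.1
POL3	msh2	F467I	85	62	110	ns	1.2
POL3	msh2	S611Y	74	57	92	ns	1.1
POL3	msh2	R658G	120	99	150	0.048	1.8
POL3	msh2	A704V	160	120	190	0.0017	2.2
POL3	msh2	G818C	870	600	1200	<0.0001	12.5
pol3-01	MSH2	control	180	140	220	NA	NA
pol3-01	MSH2	S319F	6.8	4.5	9.7	<0.0001	0.04
pol3-01	MSH2	G447D	15	11	19	<0.0001	0.08
pol3-01	MSH2	F467I	9.3	6.5	13	<0.0001	0.05
pol3-01	MSH2	K559N	20	10	35	<0.0001	0.11
pol3-01	MSH2	S611Y	31	21	43	<0.0001	0.17
pol3-01	MSH2	R658G	40	29	52	<0.0001	0.22
pol3-01	MSH2	A704V	7.3	4.4	11	<0.0001	0.04
pol3-01	MSH2	G818C	7.7	3.1	16	<0.0001	0.04
pol3-01	msh2	control	11000	9100	13000	NA	NA
pol3-01	msh2	S319F	1900	1600	2300	<0.0001	0.17
pol3-01	msh2	G447D	6200	4900	7600	0.0007	0.56
pol3-01	msh2	F467I	2600	2100	3100	<0.0001	0.23
pol3-01	msh2	S611Y	5200	4100	6400	<0.0001	0.47
pol3-01	msh2	R658G	7200	5800	8800	0.017	0.65
pol3-01	msh2	A704V	1700	1400	2100	<0.0001	0.16
pol3-01	msh2	G818C	2400	1800	3200	<0.0001	0.22
pol3-L612M	MSH2	control	13	9	17	NA	NA
pol3-L612M	MSH2	S319F	5.5	3.6	7.9	0.012	0.44
pol3-L612M	MSH2	G447D	4.6	3.0	6.5	0.0006	0.37
pol3-L612M	MSH2	F467I	7.0	4.5	10	ns	0.56
pol3-L612M	MSH2	K559N	4.1	2.4	6.6	0.001	0.33
pol3-L612M	MSH2	S611Y	5.1	3.2	7.7	0.008	0.41
pol3-L612M	MSH2	R658G	6.9	3.8	11	ns	0.55
pol3-L612M	MSH2	R674G	2.7	1.1	5.1	0.0001	0.21
pol3-L612M	MSH2	Q697R	2.0	0.8	3.8	<0.0001	0.16
pol3-L612M	MSH2	A704V	3.1	2.0	4.4	<0.0001	0.24
pol3-L612M	MSH2	G818C	3.6	2.0	5.7	0.0001	0.28
pol3-L612M	msh2	control	2700	2000	3600	NA	NA
pol3-L612M	msh2	S319F	1200	990	1500	0.0004	0.45
pol3-L612M	msh2	G447D	1700	1400	2000	ns	0.63
pol3-L612M	msh2	F467I	160	120	210	<0.0001	0.06
pol3-L612M	msh2	K559N	260	210	310	<0.0001	0.10
pol3-L612M	msh2	S611Y	350	260	460	<0.0001	0.13
pol3-L612M	msh2	R658G	720	600	840	<0.0001	0.26
pol3-L612M	msh2	R674G	370	300	440	<0.0001	0.13
pol3-L612M	msh2	Q697R	490	360	630	<0.0001	0.18
pol3-L612M	msh2	A704V	230	190	280	<0.0001	0.08
pol3-L612M	msh2	G818C	810	630	1000	<0.0001	0.29
pol3-01,L612M	MSH2	S319F	640	450	860	NA	NA
pol3-01,L612M	MSH2	G447D	8000	5500	11000	NA	NA
pol3-01,L612M	MSH2	F467I	11000	8200	13000	NA	NA
pol3-01,L612M	MSH2	K559N	2.1	0.7	4.9	NA	NA
pol3-01,L612M	MSH2	S611Y	250	200	310	NA	NA
pol3-01,L612M	MSH2	R658G	8700	6900	11000	NA	NA
pol3-01,L612M	MSH2	R674G	4.6	2.0	8.8	NA	NA
pol3-01,L612M	MSH2	Q697R	17	4.2	44	NA	NA
pol3-01,L612M	MSH2	A704V	38	20	65	NA	NA
pol3-01,L612M	MSH2	G818C	8.8	1.5	27	NA	NA
pol3-01,L612M	msh2	S319F	18000	15000	21000	NA	NA
pol3-01,L612M	msh2	G447D	13000	10000	16000	NA	NA
pol3-01,L612M	msh2	F467I	21000	18000	25000	NA	NA
pol3-01,L612M	msh2	K559N	3200	2600	3800	NA	NA
pol3-01,L612M	msh2	S611Y	6400	5300	7600	NA	NA
pol3-01,L612M	msh2	R658G	55000	41000	70000	NA	NA
pol3-01,L612M	msh2	R674G	3900	2600	5400	NA	NA
pol3-01,L612M	msh2	Q697R	4400	3500	5200	NA	NA
pol3-01,L612M	msh2	A704V	5100	4000	6400	NA	NA
pol3-01,L612M	msh2	G818C	4600	3300	5900	NA	NA
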