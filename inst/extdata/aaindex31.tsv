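aa	KYTJ820101	HOPT810101	EISD840101	FAUJ830101	ZIMJ680101	PONP800101	ARGP820101	JANJ780101	WOLR810101	GRAR740102	RADA880108	CIDH920105	ZIMJ680104	KLEP840101	FAUJ880111	FAUJ880112	CHAM830107	BIGC670101	CHOC750101	FAUJ880103	CHAM820101	DAWD720101	TSAJ990101	CHOP780201	CHOP780202	CHOP780203	LEVM780101	JANJ780102	BHAR880101	VINM940101	CHOC760101
A	1.8	-0.5	0.25	0.31	0.83	12.28	0.61	27.8	1.94	8.1	-0.06	0.02	6	0	0	0	0	52.6	91.5	1	0.046	2.5	89.3	1.42	0.83	0.74	1.29	51	0.357	0.984	115
R	-4.5	3	-1.76	-1.01	0.83	11.49	0.6	94.7	-19.92	10.5	-0.84	-0.42	10.76	1	1	0	0	109.1	202	6.13	0.291	7.5	190.3	0.98	0.93	1.01	0.96	5	0.529	1.008	225
N	-3.5	0.2	-0.64	-0.6	0.09	11	0.06	60.1	-9.68	11.6	-0.48	-0.77	5.41	0	0	0	1	75.7	135.2	2.95	0.134	5	122.4	0.67	0.89	1.46	0.9	22	0.463	1.048	160
D	-3.5	3	-0.72	-0.77	0.64	10.97	0.46	60.6	-10.95	13	-0.8	-1.04	2.77	-1	0	1	1	68.4	124.5	2.78	0.105	2.5	114.4	1.01	0.54	1.52	1.04	19	0.511	1.068	150
C	2.5	-1	0.04	1.54	1.48	14.93	1.07	15.5	-1.24	5.5	1.36	0.77	5.05	0	0	0	0	68.3	117.7	2.43	0.128	3	102.5	0.7	1.19	0.96	1.11	74	0.346	0.906	135
Q	-3.5	0.2	-0.69	-0.22	0	11.28	0	68.7	-9.38	10.5	-0.73	-1.1	5.65	0	0	0	0	89.7	161.1	3.95	0.18	6	146.9	1.11	1.1	0.96	1.27	16	0.493	1.037	180
E	-3.5	3	-0.62	-0.64	0.65	11.19	0.47	68.2	-10.2	12.3	-0.77	-1.14	3.22	-1	0	1	1	84.7	155.1	3.78	0.151	5	138.8	1.51	0.37	0.95	1.44	16	0.497	1.094	190
G	-0.4	0	0.16	0	0.1	12.01	0.07	24.5	2.39	9	-0.41	-0.8	5.97	0	0	0	1	36.3	66.4	0	0	0.5	63.8	0.57	0.75	1.56	0.56	52	0.544	1.031	75
H	-3.2	-0.5	-0.4	0.13	1.1	12.84	0.61	50.7	-10.27	10.4	0.49	0.26	7.59	0	1	0	0	91.9	167.3	4.66	0.23	6	157.5	1	0.87	0.95	1.22	34	0.323	0.95	195
I	4.5	-1.8	0.73	1.8	3.07	14.77	2.22	22.8	2.15	5.2	1.31	1.81	6.02	0	0	0	0	102	168.8	4	0.186	5.5	163	1.08	1.6	0.47	0.97	66	0.462	0.927	175
L	3.8	-1.8	0.53	1.7	2.52	14.1	1.53	27.6	2.28	4.9	1.21	1.14	5.98	0	0	0	0	102	167.9	4	0.186	5.5	163.1	1.21	1.3	0.5	1.3	60	0.365	0.935	170
K	-3.9	3	-1.1	-0.99	1.6	10.8	1.15	103	-9.52	11.3	-1.18	-0.41	9.74	1	1	0	0	105.1	171.3	4.77	0.219	7	165.1	1.16	0.74	1.19	1.23	3	0.466	1.102	200
M	1.9	-1.3	0.26	1.23	1.4	14.33	1.18	33.5	-1.48	5.7	1.27	1	5.74	0	0	0	0	97.7	170.8	4.43	0.221	6	165.8	1.45	1.05	0.6	1.47	52	0.295	0.952	185
F	2.8	-2.5	0.61	1.79	2.75	13.43	2.02	25.5	-0.76	5.2	1.27	1.35	5.48	0	0	0	0	113.9	203.4	5.89	0.29	6.5	190.8	1.13	1.38	0.66	1.07	58	0.314	0.915	210
P	-1.6	0	-0.07	0.72	2.7	11.19	1.95	51.5	-3.68	8	0	-0.09	6.3	0	0	0	0	73.6	129.3	2.72	0.131	5.5	121.6	0.57	0.55	1.56	0.52	25	0.509	1.049	145
S	-0.8	0.3	-0.26	-0.04	0.14	11.26	0.05	42	-5.06	9.2	-0.5	-0.97	5.68	0	0	0	0	54.9	99.1	1.6	0.062	3	94.2	0.77	0.75	1.43	0.82	35	0.507	1.046	115
T	-0.7	-0.4	-0.18	0.26	0.54	11.65	0.05	45	-4.88	8.6	-0.27	-0.77	5.66	0	0	0	0	71.2	122.1	2.6	0.108	5	119.6	0.83	1.19	0.98	0.82	30	0.444	0.997	140
W	-0.9	-3.4	0.37	2.25	0.31	12.95	2.65	34.7	-5.88	5.4	0.88	1.71	5.89	0	0	0	0	135.4	237.6	8.08	0.409	7	226.4	1.08	1.37	0.6	0.99	49	0.305	0.904	255
Y	-1.3	-2.3	0.02	0.96	2.97	13.29	1.88	55.2	-6.11	6.2	0.33	1.11	5.66	0	0	0	0	116.2	203.6	6.47	0.298	7	194.6	0.69	1.47	1.14	0.72	24	0.42	0.929	230
V	4.2	-1.5	0.54	1.22	1.79	15.07	1.32	23.7	1.99	5.9	1.09	1.13	5.96	0	0	0	0	85.1	141.7	3	0.14	5	138.2	1.06	1.7	0.59	0.91	64	0.386	0.931	155
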