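MutationType	ToyType1::S001	ToyType1::S002	ToyType1::S003	ToyType1::S004
A[C>A]A	400	352	220	660
A[C>A]C	522	487	391	1040
A[C>A]G	651	530	384	1332
A[C>A]T	139	127	103	247
C[C>A]A	194	263	210	600
C[C>A]C	385	371	213	793
C[C>A]G	400	486	277	924
C[C>A]T	442	608	425	1027
G[C>A]A	110	130	106	259
G[C>A]C	232	331	161	467
G[C>A]G	351	388	258	665
G[C>A]T	476	555	514	828
T[C>A]A	653	606	404	1382
T[C>A]C	185	100	96	224
T[C>A]G	342	216	211	504
T[C>A]T	332	448	242	650
A[C>G]A	726	163	65	14
A[C>G]C	1024	154	81	10
A[C>G]G	197	62	18	9
A[C>G]T	295	82	46	9
C[C>G]A	583	159	40	18
C[C>G]C	603	151	56	16
C[C>G]G	894	198	51	8
C[C>G]T	216	47	17	20
G[C>G]A	401	73	34	14
G[C>G]C	597	107	42	9
G[C>G]G	679	140	58	15
G[C>G]T	763	206	73	17
T[C>G]A	174	50	19	21
T[C>G]C	335	113	20	30
T[C>G]G	548	146	39	15
T[C>G]T	868	151	46	13
A[C>T]A	145	476	34	53
A[C>T]C	55	101	11	19
A[C>T]G	78	197	9	27
A[C>T]T	108	333	15	45
C[C>T]A	130	266	19	47
C[C>T]C	171	426	39	47
C[C>T]G	46	108	8	28
C[C>T]T	96	171	20	37
G[C>T]A	112	262	22	40
G[C>T]C	131	374	22	49
G[C>T]G	221	639	43	64
G[C>T]T	52	85	14	26
T[C>T]A	88	178	23	21
T[C>T]C	108	222	18	36
T[C>T]G	151	438	24	45
T[C>T]T	142	539	36	54
A[T>A]A	85	18	6	9
A[T>A]C	176	15	6	22
A[T>A]G	272	15	10	11
A[T>A]T	332	6	8	21
C[T>A]A	385	24	9	13
C[T>A]C	110	11	2	27
C[T>A]G	118	13	4	24
C[T>A]T	245	16	9	12
G[T>A]A	331	15	3	12
G[T>A]C	464	22	4	20
G[T>A]G	104	14	5	6
G[T>A]T	170	18	10	18
T[T>A]A	307	22	6	19
T[T>A]C	308	16	6	20
T[T>A]G	394	25	5	16
T[T>A]T	91	18	8	10
A[T>C]A	84	9	7	16
A[T>C]C	92	13	9	7
A[T>C]G	138	25	3	16
A[T>C]T	107	19	7	16
C[T>C]A	38	19	3	13
C[T>C]C	61	10	11	12
C[T>C]G	77	10	5	14
C[T>C]T	134	10	8	12
G[T>C]A	131	17	10	16
G[T>C]C	51	18	5	12
G[T>C]G	84	11	7	10
G[T>C]T	99	12	3	11
T[T>C]A	108	10	5	14
T[T>C]C	129	16	6	16
T[T>C]G	53	14	6	11
T[T>C]T	85	17	12	18
A[T>G]A	83	11	6	14
A[T>G]C	77	9	8	22
A[T>G]G	119	9	8	16
A[T>G]T	41	9	8	12
C[T>G]A	67	15	4	19
C[T>G]C	84	11	8	8
C[T>G]G	93	14	5	14
C[T>G]T	125	14	5	10
G[T>G]A	46	16	5	10
G[T>G]C	61	15	8	11
G[T>G]G	69	15	8	9
G[T>G]T	142	13	4	11
T[T>G]A	124	12	6	19
T[T>G]C	49	8	6	20
T[T>G]G	75	14	6	8
T[T>G]T	96	9	3	26
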