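label	kappa	kappa_core	lambda	lambda_core
L1	D	1	Q	1
L2	I	1	S	1
L3	Q	1	A	1
L4	M	1	L	1
L5	T	1	T	1
L6	Q	1	Q	1
L7	S	1	P	1
L8	P	1	A	1
L9	S	1	S	1
L10	S	1	S	0
L11	L	1	V	1
L12	S	1	S	1
L13	A	1	G	1
L14	S	1	S	1
L15	V	1	P	1
L16	G	1	G	1
L17	D	1	Q	1
L18	R	1	S	1
L19	V	1	I	1
L20	T	1	T	1
L21	I	1	I	1
L22	T	1	S	1
L23	C	1	C	1
L24	R	1	T	1
L25	A	1	G	1
L26	S	1	T	1
L27	Q	1	S	1
L28	S	1	S	1
L29	I	1	D	1
L30	S	1	V	1
L30A	S	0	G	1
L30B	S	0	G	1
L30C	S	0	Y	1
L30D	S	0	S	0
L30E	S	0	S	0
L30F	S	0	S	0
L30G	S	0	S	0
L31	S	1	N	1
L32	Y	1	Y	1
L33	L	1	V	1
L34	N	1	S	1
L35	W	1	W	1
L36	Y	1	Y	1
L37	Q	1	Q	1
L38	Q	1	Q	1
L39	K	1	H	1
L40	P	1	P	1
L41	G	1	G	1
L42	K	1	K	1
L43	A	1	A	1
L44	P	1	P	1
L45	K	1	K	1
L46	L	1	L	1
L47	L	1	M	1
L48	I	1	I	1
L49	Y	1	Y	1
L50	A	1	E	1
L51	A	1	V	1
L52	S	1	S	1
L53	S	1	N	1
L54	L	1	R	1
L55	Q	1	P	1
L56	S	1	S	1
L57	G	1	G	1
L58	V	1	V	1
L59	P	1	S	1
L60	S	1	N	1
L61	R	1	R	1
L62	F	1	F	1
L63	S	1	S	1
L64	G	1	G	1
L65	S	1	S	1
L66	G	1	K	1
L67	S	1	S	1
L68	G	1	G	1
L69	T	1	N	1
L70	D	1	T	1
L71	F	1	A	1
L72	T	1	S	1
L73	L	1	L	1
L74	T	1	T	1
L75	I	1	I	1
L76	S	1	S	1
L77	S	1	G	1
L78	L	1	L	1
L79	Q	1	Q	1
L80	P	1	A	1
L81	E	1	E	1
L82	D	1	D	1
L83	F	1	E	1
L84	A	1	A	1
L85	T	1	D	1
L86	Y	1	Y	1
L87	Y	1	Y	1
L88	C	1	C	1
L89	Q	1	S	1
L90	Q	1	S	1
L91	S	1	Y	1
L92	Y	1	T	1
L93	S	1	S	1
L94	T	1	S	1
L95	P	1	S	1
L95A	S	0	T	1
L95B	S	0	S	0
L95C	S	0	S	0
L95D	S	0	S	0
L95E	S	0	S	0
L95F	S	0	S	0
L95G	S	0	S	0
L96	P	1	L	1
L97	T	1	V	1
L98	F	1	F	1
L99	G	1	G	1
L100	Q	1	G	1
L101	G	1	G	1
L102	T	1	T	1
L103	K	1	K	1
L104	V	1	L	1
L105	E	1	T	1
L106	I	1	V	1
L106A	S	0	S	0
L107	K	1	L	1
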