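label	consensus	core
H1	E	1
H2	V	1
H3	Q	1
H4	L	1
H5	L	1
H6	E	1
H7	S	1
H8	G	1
H9	G	1
H10	G	1
H11	L	1
H12	V	1
H13	Q	1
H14	P	1
H15	G	1
H16	G	1
H17	S	1
H18	L	1
H19	R	1
H20	L	1
H21	S	1
H22	C	1
H23	A	1
H24	A	1
H25	S	1
H26	G	1
H27	F	1
H28	T	1
H29	F	1
H30	S	1
H31	S	1
H31A	S	0
H31B	S	0
H32	Y	1
H33	A	1
H34	M	1
H35	S	1
H36	W	1
H37	V	1
H38	R	1
H39	Q	1
H40	A	1
H41	P	1
H42	G	1
H43	K	1
H44	G	1
H45	L	1
H46	E	1
H47	W	1
H48	V	1
H49	S	1
H50	A	1
H51	I	1
H52	S	1
H52A	G	1
H52B	G	0
H52C	S	0
H53	S	1
H54	G	1
H55	G	1
H56	S	1
H57	T	1
H58	Y	1
H59	Y	1
H60	A	1
H61	D	1
H62	S	1
H63	V	1
H64	K	1
H65	G	1
H66	R	1
H67	F	1
H68	T	1
H69	I	1
H70	S	1
H71	R	1
H72	D	1
H73	N	1
H74	S	1
H75	K	1
H76	N	1
H77	T	1
H78	L	1
H79	Y	1
H80	L	1
H81	Q	1
H82	M	1
H82A	N	1
H82B	S	1
H82C	L	1
H83	R	1
H84	A	1
H85	E	1
H86	D	1
H87	T	1
H88	A	1
H89	V	1
H90	Y	1
H91	Y	1
H92	C	1
H93	A	1
H94	K	1
H95	D	1
H96	G	1
H97	G	1
H98	Y	1
H99	S	1
H100	G	1
H100A	S	0
H100B	S	0
H100C	G	0
H100D	Y	0
H100E	Y	0
H100F	S	0
H100G	S	0
H100H	G	0
H100I	Y	0
H100J	Y	0
H100K	S	0
H101	D	1
H102	Y	1
H103	W	1
H104	G	1
H105	Q	1
H106	G	1
H107	T	1
H108	L	1
H109	V	1
H110	T	1
H111	V	1
H112	S	1
H113	S	1
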