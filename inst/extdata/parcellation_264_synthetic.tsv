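roi_id	x	y	z	network
ROI_001	65	-88	-11	DMN
ROI_002	-6	-96	18	DMN
ROI_003	-35	-40	19	DMN
ROI_004	-49	-86	60	DMN
ROI_005	-28	-47	-4	DMN
ROI_006	-39	-37	4	DMN
ROI_007	28	-52	-35	DMN
ROI_008	67	-26	43	DMN
ROI_009	-49	-51	-34	DMN
ROI_010	-14	56	-30	DMN
ROI_011	-18	-4	18	DMN
ROI_012	62	54	-24	DMN
ROI_013	21	-74	28	DMN
ROI_014	-25	63	59	DMN
ROI_015	66	-34	24	DMN
ROI_016	7	-101	12	DMN
ROI_017	64	-75	-34	DMN
ROI_018	-19	18	-22	DMN
ROI_019	59	-90	5	DMN
ROI_020	-46	-52	3	DMN
ROI_021	-6	12	9	DMN
ROI_022	5	-5	-1	DMN
ROI_023	-35	-39	-28	DMN
ROI_024	-61	-33	14	DMN
ROI_025	-6	7	5	DMN
ROI_026	-34	-84	26	DMN
ROI_027	22	-11	-11	DMN
ROI_028	-15	57	42	DMN
ROI_029	-3	18	-5	DMN
ROI_030	-63	-24	19	DMN
ROI_031	10	53	-29	DMN
ROI_032	39	-47	-18	DMN
ROI_033	58	-72	15	DMN
ROI_034	19	-14	-30	DMN
ROI_035	-28	-3	31	DMN
ROI_036	39	-73	44	DMN
ROI_037	26	-66	-17	DMN
ROI_038	-55	-35	-30	DMN
ROI_039	-2	-54	31	DMN
ROI_040	-42	-79	33	DMN
ROI_041	58	-69	-39	DMN
ROI_042	-9	-47	-45	DMN
ROI_043	8	-43	53	DMN
ROI_044	7	-85	27	DMN
ROI_045	48	-26	62	DMN
ROI_046	17	41	17	DMN
ROI_047	-2	-65	-40	DMN
ROI_048	-4	-94	-20	DMN
ROI_049	-40	43	4	DMN
ROI_050	-35	36	-13	DMN
ROI_051	31	-29	-42	DMN
ROI_052	-33	-82	4	DMN
ROI_053	-31	28	-30	DMN
ROI_054	-32	-63	-20	DMN
ROI_055	-69	8	-43	DMN
ROI_056	-24	8	71	DMN
ROI_057	31	32	53	DMN
ROI_058	-19	-27	7	DMN
ROI_059	7	25	70	SMN
ROI_060	-18	29	57	SMN
ROI_061	-43	-19	-35	SMN
ROI_062	-36	-86	12	SMN
ROI_063	-65	49	-10	SMN
ROI_064	-20	-4	-32	SMN
ROI_065	-26	14	50	SMN
ROI_066	50	-24	-19	SMN
ROI_067	-42	61	70	SMN
ROI_068	51	-25	-35	SMN
ROI_069	6	-83	16	SMN
ROI_070	6	17	-4	SMN
ROI_071	-41	-51	-21	SMN
ROI_072	26	-54	42	SMN
ROI_073	10	61	-25	SMN
ROI_074	62	-89	62	SMN
ROI_075	34	12	32	SMN
ROI_076	63	45	28	SMN
ROI_077	24	-62	18	SMN
ROI_078	31	36	45	SMN
ROI_079	5	-38	-36	SMN
ROI_080	-33	6	-39	SMN
ROI_081	33	-34	-36	SMN
ROI_082	-42	-28	-13	SMN
ROI_083	-25	10	17	SMN
ROI_084	-5	56	8	SMN
ROI_085	26	-74	10	SMN
ROI_086	-10	-85	-19	SMN
ROI_087	-17	-56	21	SMN
ROI_088	8	-56	47	SMN
ROI_089	19	-14	-36	SMN
ROI_090	14	-4	-28	SMN
ROI_091	0	-82	57	SMN
ROI_092	-49	-30	-5	SMN
ROI_093	-44	-45	8	SMN
ROI_094	-51	-95	23	CON
ROI_095	-68	-19	-19	CON
ROI_096	44	55	11	CON
ROI_097	2	7	64	CON
ROI_098	55	-30	-43	CON
ROI_099	-49	-9	67	CON
ROI_100	48	0	2	CON
ROI_101	-69	-60	10	CON
ROI_102	-25	62	66	CON
ROI_103	50	-92	-10	CON
ROI_104	66	4	2	CON
ROI_105	4	48	53	CON
ROI_106	-68	69	20	CON
ROI_107	-25	-3	73	CON
ROI_108	-18	-95	-13	AUD
ROI_109	28	37	16	AUD
ROI_110	60	-61	-6	AUD
ROI_111	58	57	74	AUD
ROI_112	-40	-38	-9	AUD
ROI_113	46	-90	63	AUD
ROI_114	21	-17	28	AUD
ROI_115	39	23	19	AUD
ROI_116	49	37	-19	AUD
ROI_117	21	59	-11	AUD
ROI_118	-13	16	-4	AUD
ROI_119	7	-6	43	AUD
ROI_120	58	58	-23	AUD
ROI_121	63	-48	45	VIS
ROI_122	19	-36	3	VIS
ROI_123	13	-71	12	VIS
ROI_124	-67	-61	-27	VIS
ROI_125	14	-35	35	VIS
ROI_126	2	-7	58	VIS
ROI_127	29	61	-27	VIS
ROI_128	-52	-67	12	VIS
ROI_129	-13	13	48	VIS
ROI_130	38	-80	-15	VIS
ROI_131	-57	53	36	VIS
ROI_132	53	13	-7	VIS
ROI_133	26	8	60	VIS
ROI_134	-37	23	16	VIS
ROI_135	-65	-62	29	VIS
ROI_136	-11	32	24	VIS
ROI_137	-42	-53	6	VIS
ROI_138	56	54	39	VIS
ROI_139	69	67	-4	VIS
ROI_140	4	-103	69	VIS
ROI_141	-25	65	46	VIS
ROI_142	-47	21	50	VIS
ROI_143	66	-78	28	VIS
ROI_144	61	15	2	VIS
ROI_145	18	-103	74	VIS
ROI_146	-50	-86	9	VIS
ROI_147	40	-21	6	VIS
ROI_148	30	-33	-24	VIS
ROI_149	-21	-71	74	VIS
ROI_150	34	-102	51	VIS
ROI_151	-38	35	-21	VIS
ROI_152	-61	43	-19	MEM
ROI_153	-63	32	-34	MEM
ROI_154	69	10	73	MEM
ROI_155	64	-33	35	MEM
ROI_156	35	-101	44	MEM
ROI_157	-12	-73	-31	FPN
ROI_158	-46	-105	-27	FPN
ROI_159	-26	-77	55	FPN
ROI_160	66	-3	50	FPN
ROI_161	33	15	50	FPN
ROI_162	-7	69	20	FPN
ROI_163	-21	4	3	FPN
ROI_164	17	9	38	FPN
ROI_165	-60	38	-20	FPN
ROI_166	60	-58	72	FPN
ROI_167	-55	64	42	FPN
ROI_168	29	-43	2	FPN
ROI_169	41	-94	5	FPN
ROI_170	-52	36	-4	FPN
ROI_171	-54	-57	37	FPN
ROI_172	-63	-82	24	FPN
ROI_173	30	-2	3	FPN
ROI_174	-15	-66	8	FPN
ROI_175	-24	-91	-44	FPN
ROI_176	50	17	-40	FPN
ROI_177	39	1	2	FPN
ROI_178	61	-79	22	FPN
ROI_179	-49	-5	52	FPN
ROI_180	57	8	26	FPN
ROI_181	5	-22	26	FPN
ROI_182	-46	37	-37	SAN
ROI_183	30	-40	-20	SAN
ROI_184	-36	-74	8	SAN
ROI_185	-65	-2	2	SAN
ROI_186	-38	6	44	SAN
ROI_187	39	-35	73	SAN
ROI_188	-52	-74	42	SAN
ROI_189	-52	-56	18	SAN
ROI_190	67	59	-20	SAN
ROI_191	65	-93	8	SAN
ROI_192	-38	-101	15	SAN
ROI_193	-27	27	17	SAN
ROI_194	-52	39	5	SAN
ROI_195	-48	-24	-26	SAN
ROI_196	-7	67	14	SAN
ROI_197	-12	-78	7	SAN
ROI_198	64	-85	64	SAN
ROI_199	8	-43	-8	SAN
ROI_200	-39	-20	54	SC
ROI_201	39	21	-7	SC
ROI_202	-44	-79	12	SC
ROI_203	35	-60	-29	SC
ROI_204	47	22	68	SC
ROI_205	-41	27	-33	SC
ROI_206	-13	-47	13	SC
ROI_207	49	-18	-37	SC
ROI_208	17	-94	20	SC
ROI_209	-34	-88	69	SC
ROI_210	24	-32	-37	SC
ROI_211	-2	51	68	SC
ROI_212	-50	13	46	SC
ROI_213	-32	22	53	VAN
ROI_214	17	29	12	VAN
ROI_215	10	-23	3	VAN
ROI_216	-33	-71	-11	VAN
ROI_217	62	10	58	VAN
ROI_218	55	-102	19	VAN
ROI_219	-51	24	-17	VAN
ROI_220	-62	42	-16	VAN
ROI_221	44	6	4	VAN
ROI_222	37	-87	57	DAN
ROI_223	-66	46	20	DAN
ROI_224	-54	-99	62	DAN
ROI_225	31	1	40	DAN
ROI_226	46	-44	-6	DAN
ROI_227	-41	3	-1	DAN
ROI_228	10	-81	71	DAN
ROI_229	60	32	-26	DAN
ROI_230	-50	-27	-19	DAN
ROI_231	25	54	7	DAN
ROI_232	45	-45	21	DAN
ROI_233	46	10	-18	CB
ROI_234	40	-31	60	CB
ROI_235	42	-59	74	CB
ROI_236	8	30	-6	CB
ROI_237	37	69	10	Uncertain
ROI_238	-4	-18	18	Uncertain
ROI_239	-19	-11	58	Uncertain
ROI_240	31	-59	-7	Uncertain
ROI_241	-50	39	26	Uncertain
ROI_242	-2	56	-30	Uncertain
ROI_243	-36	-82	6	Uncertain
ROI_244	4	-95	-33	Uncertain
ROI_245	-60	-7	-1	Uncertain
ROI_246	-17	31	50	Uncertain
ROI_247	18	-26	42	Uncertain
ROI_248	27	-86	-3	Uncertain
ROI_249	-52	-82	70	Uncertain
ROI_250	-36	-67	47	Uncertain
ROI_251	-30	-96	-13	Uncertain
ROI_252	-31	-20	-15	Uncertain
ROI_253	-16	48	49	Uncertain
ROI_254	68	-66	75	Uncertain
ROI_255	45	-84	-39	Uncertain
ROI_256	-33	28	46	Uncertain
ROI_257	48	-19	25	Uncertain
ROI_258	-59	-36	21	Uncertain
ROI_259	-37	-36	32	Uncertain
ROI_260	42	-10	-29	Uncertain
ROI_261	-34	-25	4	Uncertain
ROI_262	-24	46	5	Uncertain
ROI_263	45	43	34	Uncertain
ROI_264	-19	-104	46	Uncertain
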