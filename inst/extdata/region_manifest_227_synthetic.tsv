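region	network	domain
roi_001	SMN	cortical
roi_002	SMN	cortical
roi_003	SMN	cortical
roi_004	SMN	cortical
roi_005	SMN	cortical
roi_006	SMN	cortical
roi_007	SMN	cortical
roi_008	SMN	cortical
roi_009	SMN	cortical
roi_010	SMN	cortical
roi_011	SMN	cortical
roi_012	SMN	cortical
roi_013	SMN	cortical
roi_014	SMN	cortical
roi_015	SMN	cortical
roi_016	SMN	cortical
roi_017	SMN	cortical
roi_018	SMN	cortical
roi_019	SMN	cortical
roi_020	SMN	cortical
roi_021	SMN	cortical
roi_022	SMN	cortical
roi_023	SMN	cortical
roi_024	SMN	cortical
roi_025	SMN	cortical
roi_026	SMN	cortical
roi_027	SMN	cortical
roi_028	SMN	cortical
roi_029	SMN	cortical
roi_030	SMN	cortical
roi_031	SMN	cortical
roi_032	SMN	cortical
roi_033	SMN	cortical
roi_034	SMN	cortical
roi_035	SMN	cortical
roi_036	CON	cortical
roi_037	CON	cortical
roi_038	CON	cortical
roi_039	CON	cortical
roi_040	CON	cortical
roi_041	CON	cortical
roi_042	CON	cortical
roi_043	CON	cortical
roi_044	CON	cortical
roi_045	CON	cortical
roi_046	CON	cortical
roi_047	CON	cortical
roi_048	CON	cortical
roi_049	CON	cortical
roi_050	AUN	cortical
roi_051	AUN	cortical
roi_052	AUN	cortical
roi_053	AUN	cortical
roi_054	AUN	cortical
roi_055	AUN	cortical
roi_056	AUN	cortical
roi_057	AUN	cortical
roi_058	AUN	cortical
roi_059	AUN	cortical
roi_060	AUN	cortical
roi_061	AUN	cortical
roi_062	AUN	cortical
roi_063	DMN	cortical
roi_064	DMN	cortical
roi_065	DMN	cortical
roi_066	DMN	cortical
roi_067	DMN	cortical
roi_068	DMN	cortical
roi_069	DMN	cortical
roi_070	DMN	cortical
roi_071	DMN	cortical
roi_072	DMN	cortical
roi_073	DMN	cortical
roi_074	DMN	cortical
roi_075	DMN	cortical
roi_076	DMN	cortical
roi_077	DMN	cortical
roi_078	DMN	cortical
roi_079	DMN	cortical
roi_080	DMN	cortical
roi_081	DMN	cortical
roi_082	DMN	cortical
roi_083	DMN	cortical
roi_084	DMN	cortical
roi_085	DMN	cortical
roi_086	DMN	cortical
roi_087	DMN	cortical
roi_088	DMN	cortical
roi_089	DMN	cortical
roi_090	DMN	cortical
roi_091	DMN	cortical
roi_092	DMN	cortical
roi_093	DMN	cortical
roi_094	DMN	cortical
roi_095	DMN	cortical
roi_096	DMN	cortical
roi_097	DMN	cortical
roi_098	DMN	cortical
roi_099	DMN	cortical
roi_100	DMN	cortical
roi_101	DMN	cortical
roi_102	DMN	cortical
roi_103	DMN	cortical
roi_104	DMN	cortical
roi_105	DMN	cortical
roi_106	DMN	cortical
roi_107	DMN	cortical
roi_108	DMN	cortical
roi_109	DMN	cortical
roi_110	DMN	cortical
roi_111	DMN	cortical
roi_112	DMN	cortical
roi_113	DMN	cortical
roi_114	DMN	cortical
roi_115	DMN	cortical
roi_116	DMN	cortical
roi_117	DMN	cortical
roi_118	DMN	cortical
roi_119	DMN	cortical
roi_120	DMN	cortical
roi_121	VSN	cortical
roi_122	VSN	cortical
roi_123	VSN	cortical
roi_124	VSN	cortical
roi_125	VSN	cortical
roi_126	VSN	cortical
roi_127	VSN	cortical
roi_128	VSN	cortical
roi_129	VSN	cortical
roi_130	VSN	cortical
roi_131	VSN	cortical
roi_132	VSN	cortical
roi_133	VSN	cortical
roi_134	VSN	cortical
roi_135	VSN	cortical
roi_136	VSN	cortical
roi_137	VSN	cortical
roi_138	VSN	cortical
roi_139	VSN	cortical
roi_140	VSN	cortical
roi_141	VSN	cortical
roi_142	VSN	cortical
roi_143	VSN	cortical
roi_144	VSN	cortical
roi_145	VSN	cortical
roi_146	VSN	cortical
roi_147	VSN	cortical
roi_148	VSN	cortical
roi_149	VSN	cortical
roi_150	VSN	cortical
roi_151	VSN	cortical
roi_152	FPN	cortical
roi_153	FPN	cortical
roi_154	FPN	cortical
roi_155	FPN	cortical
roi_156	FPN	cortical
roi_157	FPN	cortical
roi_158	FPN	cortical
roi_159	FPN	cortical
roi_160	FPN	cortical
roi_161	FPN	cortical
roi_162	FPN	cortical
roi_163	FPN	cortical
roi_164	FPN	cortical
roi_165	FPN	cortical
roi_166	FPN	cortical
roi_167	FPN	cortical
roi_168	FPN	cortical
roi_169	FPN	cortical
roi_170	FPN	cortical
roi_171	FPN	cortical
roi_172	FPN	cortical
roi_173	FPN	cortical
roi_174	FPN	cortical
roi_175	FPN	cortical
roi_176	FPN	cortical
roi_177	SAN	cortical
roi_178	SAN	cortical
roi_179	SAN	cortical
roi_180	SAN	cortical
roi_181	SAN	cortical
roi_182	SAN	cortical
roi_183	SAN	cortical
roi_184	SAN	cortical
roi_185	SAN	cortical
roi_186	SAN	cortical
roi_187	SAN	cortical
roi_188	SAN	cortical
roi_189	SAN	cortical
roi_190	SAN	cortical
roi_191	SAN	cortical
roi_192	SAN	cortical
roi_193	SAN	cortical
roi_194	SAN	cortical
roi_195	SUN	subcortical
roi_196	SUN	subcortical
roi_197	SUN	subcortical
roi_198	SUN	subcortical
roi_199	SUN	subcortical
roi_200	SUN	subcortical
roi_201	SUN	subcortical
roi_202	SUN	subcortical
roi_203	SUN	subcortical
roi_204	SUN	subcortical
roi_205	SUN	subcortical
roi_206	SUN	subcortical
roi_207	SUN	subcortical
roi_208	VAN	cortical
roi_209	VAN	cortical
roi_210	VAN	cortical
roi_211	VAN	cortical
roi_212	VAN	cortical
roi_213	VAN	cortical
roi_214	VAN	cortical
roi_215	VAN	cortical
roi_216	VAN	cortical
roi_217	DAN	cortical
roi_218	DAN	cortical
roi_219	DAN	cortical
roi_220	DAN	cortical
roi_221	DAN	cortical
roi_222	DAN	cortical
roi_223	DAN	cortical
roi_224	DAN	cortical
roi_225	DAN	cortical
roi_226	DAN	cortical
roi_227	DAN	cortical
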