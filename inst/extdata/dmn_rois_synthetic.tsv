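name	hemisphere	x	y	z	radius_mm
vmPFC	M	0	48	-6	6
dmPFC	M	0	52	26	6
PCC_L	L	-5	-49	33	6
LatTemp_L	L	-58	-20	-12	6
IPL_L	L	-47	-65	32	6
IPL_R	R	50	-64	32	6
PHC_L	L	-24	-36	-14	6
PHC_R	R	24	-36	-14	6
HF_L	L	-22	-20	-18	6
HF_R	R	22	-20	-18	6
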