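name	hemisphere	x	y	z	radius_mm
IPS_L	L	-26	-63	48	6
IPS_R	R	25	-60	48	6
hMT_L	L	-44	-67	3	6
hMT_R	R	44	-71	6	6
FEF_L	L	-30	-5	48	6
FEF_R	R	30	-5	48	6
TPJ_L	L	-48	-54	26	6
TPJ_R	R	48	-54	21	6
VFC_L	L	-42	12	-1	6
VFC_R	R	40	17	4	6
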