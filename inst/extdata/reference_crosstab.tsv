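lehmann_subtype	study_subtype	percent
BL1	IM	19.23
BL1	MSL	0.00
BL1	M	8.70
BL1	LAR	0.00
BL1	BL	50.00
BL2	IM	0.00
BL2	MSL	5.26
BL2	M	8.70
BL2	LAR	3.03
BL2	BL	4.55
IM	IM	53.85
IM	MSL	26.32
IM	M	13.04
IM	LAR	0.00
IM	BL	0.00
M	IM	19.23
M	MSL	5.26
M	M	34.78
M	LAR	9.09
M	BL	13.64
MSL	IM	0.00
MSL	MSL	52.63
MSL	M	13.04
MSL	LAR	24.24
MSL	BL	4.55
LAR	IM	3.85
LAR	MSL	10.53
LAR	M	0.00
LAR	LAR	63.64
LAR	BL	4.55
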