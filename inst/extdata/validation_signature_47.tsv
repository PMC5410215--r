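subtype	direction	gene	symbol
IM	up	232362_at	CCDC18
IM	up	206486_at	LAG3
IM	up	207634_at	PDCD1
IM	up	223834_at	CD274
IM	up	220049_s_at	PDCD1LG2
IM	up	222835_at	THSD4
IM	up	228708_at	RAB27B
IM	up	209505_at	NR2F1
IM	up	226553_at	TMPRSS2
IM	up	213823_at	HOXA11
MSL	up	227427_at	ARHGEF25
MSL	up	206485_at	CD5
MSL	up	217190_x_at	ESR1
MSL	up	211233_x_at	ESR1
MSL	up	215104_at	NRIP2
MSL	up	229377_at	GRTP1
MSL	up	244264_at	KLRG2
MSL	up	232179_at	LOC158863
MSL	up	236390_at	SLX4IP
MSL	up	232001_at	PRKCQ-AS1
M	up	201268_at	NME1-NME2
M	up	213801_x_at	RPSA
M	up	200023_s_at	EIF3F
M	up	215157_x_at	PABPC1
M	up	228256_s_at	EPB41L4A
M	up	205990_s_at	WNT5A
M	up	226192_at	AR
M	up	204014_at	DUSP4
M	up	203963_at	CA12
LAR	up	218211_s_at	MLPH
LAR	up	215465_s_at	ABCA12
LAR	up	232914_s_at	SYTL2
LAR	up	212510_at	GPD1L
LAR	up	227733_at	TMEM63C
LAR	up	235020_at	TAF4B
LAR	up	209138_x_at	IGLC1
LAR	up	225973_at	TAP2
LAR	up	223307_at	CDCA3
BL	up	219787_s_at	ECT2
BL	up	231984_at	MTAP
BL	up	229538_s_at	IQGAP3
BL	up	208165_s_at	PRSS16
BL	up	226189_at	ITGB8
BL	up	212998_x_at	HLA-DQB1
BL	up	215536_at	HLA-DQB2
BL	up	204149_s_at	GSTM4
BL	up	214123_s_at	NOP14-AS1
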