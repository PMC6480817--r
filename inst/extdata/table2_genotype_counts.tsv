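population	n	VV	VG	GG	II	IT	TT	FF	FS	FL	SS
CP	30	26	2	2	26	4	0	30	0	0	0
PJY	24	23	1	0	11	11	2	24	0	0	0
OFP	27	25	2	0	7	11	9	26	1	0	0
DC	28	20	8	0	8	16	4	28	0	0	0
DX	25	19	5	1	12	10	3	24	1	0	0
FS	26	25	1	0	25	0	1	25	1	0	0
FT	26	19	6	1	11	9	6	26	0	0	0
HD	17	0	12	5	10	7	0	17	0	0	0
HR	27	27	0	0	27	0	0	27	0	0	0
MTG	25	24	1	0	21	4	0	25	0	0	0
MY	27	26	1	0	27	0	0	27	0	0	0
PG	25	25	0	0	8	8	9	25	0	0	0
SJS	23	14	7	2	14	8	1	21	2	0	0
SY	18	18	0	0	15	3	0	18	0	0	0
TZ	29	24	5	0	13	15	1	13	14	1	1
XC	25	21	4	0	8	11	6	25	0	0	0
YQ	24	24	0	0	22	2	0	24	0	0	0
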