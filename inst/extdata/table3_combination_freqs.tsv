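type	gt_1016	gt_1532	gt_1534	CP	OFP	PJY	DC	DX	FS	FT	HD	HR	MTG	MY	PG	SJS	SY	TZ	XC	YQ
1	V/V	I/I	F/F	0.733	0.185	0.417	0.179	0.320	0.885	0.308	0	1.000	0.800	0.963	0.320	0.261	0.833	0.103	0.240	0.917
2	G/G	I/I	F/F	0.067	0	0	0	0.040	0	0.038	0.294	0	0	0	0	0.087	0	0	0	0
3	V/V	T/T	F/F	0	0.333	0.083	0.143	0.120	0.038	0.231	0	0	0	0	0.360	0.043	0	0.034	0.240	0
4	V/V	I/I	S/S	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0.034	0	0
5	V/G	I/I	F/F	0.067	0.037	0.042	0.107	0.120	0.038	0.077	0.294	0	0.040	0.037	0	0.261	0	0.103	0.080	0
6	V/V	I/T	F/F	0.133	0.407	0.458	0.393	0.280	0	0.192	0	0	0.160	0	0.320	0.217	0.167	0.172	0.360	0.083
7	V/V	I/I	F/S	0	0	0	0	0	0.038	0	0	0	0	0	0	0	0	0.138	0	0
8	V/V	I/I	F/L	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0.034	0	0
9	V/G	I/T	F/F	0	0	0	0.179	0.080	0	0.154	0.412	0	0	0	0	0.043	0	0.034	0.080	0
10	V/V	I/T	F/S	0	0	0	0	0.040	0	0	0	0	0	0	0	0.087	0	0.310	0	0
11	V/G	I/I	F/S	0	0.037	0	0	0	0	0	0	0	0	0	0	0	0	0.034	0	0
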