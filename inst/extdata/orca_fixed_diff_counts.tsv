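pop	n	SR	AR	BS	RU	OS	AT	CT	IC	MI
SR	13	0	0	0	0	8	7	5	15	9
AR	17	0	0	0	0	5	3	2	12	6
BS	13	0	0	0	0	5	3	2	9	5
RU	9	0	0	0	0	4	3	2	7	4
OS	7	5	1	0	0	0	1	1	7	2
AT	21	0	0	0	0	0	0	0	1	0
CT	16	0	0	0	0	0	0	0	0	0
IC	6	6	4	3	3	2	0	0	0	0
MI	13	2	0	0	0	0	0	0	0	0
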