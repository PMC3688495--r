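gene_id	ctl_t1_r1	ctl_t1_r2	trt_t1_r1	trt_t1_r2
g1	100	110	95	105
g2	5	3	400	380
g3	4	6	350	360
g4	7	5	390	410
g5	120	130	125	118
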