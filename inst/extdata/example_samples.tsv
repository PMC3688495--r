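sample_id	condition	timepoint	replicate
ctl_t1_r1	control	1	1
ctl_t1_r2	control	1	2
trt_t1_r1	treatment	1	1
trt_t1_r2	treatment	1	2
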