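ovary_id	stage	sum_Q	f1	f2	f3
ov_36L	primordial	41	1	0.333333333333333	0.1
ov_36L	primary	4	1	0.333333333333333	0.1
ov_36L	secondary	0	1	0.333333333333333	0.1
ov_36L	antral	0	1	0.333333333333333	0.1
ov_36R	primordial	36	0.92	0.4	0.1
ov_36R	primary	3	0.92	0.4	0.1
ov_36R	secondary	1	0.92	0.4	0.1
ov_36R	antral	0	0.92	0.4	0.1
ov_47L	primordial	4	1	0.3	0.1
ov_47L	primary	1	1	0.3	0.1
ov_47L	secondary	0	1	0.3	0.1
ov_47L	antral	0	1	0.3	0.1
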