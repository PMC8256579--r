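run_start	run_end	run_base	kind	position	ref_allele	alt_allele	group_id	n_mutants	n_independent
8	12	A	deletion	8	A		ko_vehicle	3	1
8	12	A	deletion	8	A		ko_kbro3	6	3
88	90	A	deletion	88	A		ko_vehicle	1	1
88	90	A	deletion	88	A		ko_kbro3	2	1
173	175	T	substitution	175	T	C	ko_kbro3	2	1
179	181	T	substitution	181	T	C	ko_kbro3	1	1
179	181	T	insertion	178		T	ko_kbro3	1	1
214	216	A	insertion	213		A	ko_kbro3	1	1
223	225	A	deletion	223	A		ko_vehicle	1	1
223	225	A	deletion	223	A		ko_kbro3	2	2
315	318	A	deletion	315	A		ko_vehicle	4	1
315	318	A	deletion	315	A		ko_kbro3	3	3
325	327	T	deletion	325	T		ko_kbro3	1	1
342	345	A	deletion	342	A		ko_vehicle	2	1
342	345	A	deletion	342	A		ko_kbro3	5	2
342	345	A	insertion	341		AA	ko_kbro3	2	1
342	345	A	insertion	341		A	ko_kbro3	2	2
342	345	A	substitution	345	A	C	ko_vehicle	1	1
342	345	A	substitution	345	A	C	ko_kbro3	2	2
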