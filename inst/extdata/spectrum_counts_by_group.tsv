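category	bearing_vehicle	bearing_kbro3	ko_vehicle	ko_kbro3
GC_to_AT	3	10	51	60
GC_to_AT_CpG	1	8	20	35
AT_to_GC	0	2	13	25
GC_to_TA	2	8	10	19
GC_to_CG	0	1	0	1
AT_to_TA	0	2	4	2
AT_to_CG	1	0	6	2
deletion_1	2	2	17	26
deletion_ge2	1	3	0	0
insertion	1	0	6	12
other	0	0	0	2
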