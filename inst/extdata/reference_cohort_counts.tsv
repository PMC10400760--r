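stratum	n	n_female	n_blood	n_saliva	n_buccal	n_urine
age_110plus	25	20	20	2	3	0
age_100plus	184	128	175	6	3	0
age_90plus	358	220	349	6	3	0
age_80plus	1262	672	1253	6	3	0
age_40plus	7039	3838	7030	6	3	0
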