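field	value
verdict	undetermined
density_snp_per_kb	0.625
partition_score	1
permutation_p	1
partition.nucleus_01	A
partition.nucleus_02	B
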