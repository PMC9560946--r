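field	value
n_sites_input	418
n_failed_hard_filters	17
n_cells_masked	4
n_sites_removed_missingness	85
n_snp_sites	27
n_snp_sites_all_alt	0
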