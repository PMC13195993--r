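sample_id	n_complete_reads	n_expanded_reads	span_min_bp	span_median_bp	span_max_bp	units_min	units_median	units_max	fraction_tctg_percent	units_cctg_min	units_cctg_median	units_cctg_max	units_tctg_min	units_tctg_median	units_tctg_max
demo	30	30	1750	2673	3969	437	668	992	60.0	414	575	965	0	108	119
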