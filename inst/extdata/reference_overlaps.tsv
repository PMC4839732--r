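quantity	value
genes_microarray	1011
genes_rnai	957
genes_overlap	78
universe_detected	12363
screen_orfs	13826
pathways_rnai	41
pathways_microarray	29
pathways_overlap	4
hits_tested	29
hits_validated	21
printed_gene_overlap_percent	4.1
printed_pathway_overlap_percent	6.1
printed_validation_percent	72
printed_gene_overlap_p_bound	0.73
printed_pathway_overlap_p_bound	0.44
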