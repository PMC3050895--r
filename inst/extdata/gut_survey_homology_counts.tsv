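quantity	count
non_rrna_reads	27923
protein_homologs	14680
cog_assigned	6975
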