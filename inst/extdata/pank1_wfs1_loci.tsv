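locus_id	chrom	gwas_flag
PANK1	10	TRUE
WFS1	4	TRUE
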