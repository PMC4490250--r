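locus_id	chrom	gwas_flag
IGF2BP2	3	TRUE
HNF1A	12	TRUE
GRM5	11	FALSE
LIPC/HDLCQ12	15	FALSE
PRKG1	10	FALSE
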