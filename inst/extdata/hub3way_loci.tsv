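locus_id	chrom	gwas_flag
TM6SF2	19	TRUE
SUGP1	19	FALSE
LPP	3	FALSE
KCNIP3	2	FALSE
CTRB1/BCAR1	16	TRUE
CELSR2/PSRC1	1	TRUE
SORT1	1	FALSE
NOTCH2	1	FALSE
BCAR3	1	FALSE
21q22.3	21	FALSE
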