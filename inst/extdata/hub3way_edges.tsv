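locus_u	locus_v	layer	evidence
TM6SF2	SUGP1	spatial	encode_contact
TM6SF2	LPP	spatial	encode_contact
TM6SF2	KCNIP3	spatial	encode_contact
KCNIP3	CTRB1/BCAR1	spatial	encode_contact
CELSR2/PSRC1	SORT1	spatial	encode_contact
CELSR2/PSRC1	NOTCH2	spatial	encode_contact
CELSR2/PSRC1	BCAR3	spatial	encode_contact
CELSR2/PSRC1	21q22.3	spatial	encode_contact
CTRB1/BCAR1	BCAR3	functional	bcar1_bcar3_protein_interaction
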