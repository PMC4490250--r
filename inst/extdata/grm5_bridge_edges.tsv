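locus_u	locus_v	layer	evidence
IGF2BP2	GRM5	spatial	encode_contact
HNF1A	GRM5	spatial	encode_contact
IGF2BP2	LIPC/HDLCQ12	spatial	encode_contact
HNF1A	PRKG1	spatial	encode_contact
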