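rsid	chrom	pos	gene	study
rs16860235	3	185512361	IGF2BP2	meta1
rs1169288	12	120978847	HNF1A	meta5
rs2001844	8	126478745	NA	meta5
rs6909	19	19619542	GATAD2A	meta2
rs7798124	7	15055616	NA	meta1
rs7168849	15	90346227	ANPEP	meta1
rs7111	15	90373873	AP3S2	meta1
rs11755566	6	38116669	ZFAND3	meta1
rs3741530	12	123469647	ABCB9/PITPNM2	meta3
rs703977	10	944230	ZMIZ1	meta1
rs11683087	2	227586606	IRS1	meta7
rs174535	11	61551356	MYRF	meta5
rs7202844	16	75247391	CTRB1/BCAR1	meta1
rs10160034	10	91352850	PANK1	meta2
rs1801214	4	6303022	WFS1	meta1
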