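# Chromosomal structure variation across 11 materials of three species,
# transcribed from the printed survey table. Cells: + present, - absent,
# 0 subgenome absent in the species; trailing ' marks the printed
# species-specific superscript, '' the possibly-ancestral superscript
# (annotations are carried for cross-checking only, never computed on).
# Rows whose printed label compressed several CRs are split one per CR.
#material Hbw H_bogdanii
#material DY E_sibiricus
#material GEM E_sibiricus
#material KB E_sibiricus
#material XN E_sibiricus
#material NM E_sibiricus
#material LJS E_sibiricus
#material PJC E_nutans
#material B05 E_nutans
#material H11 E_nutans
#material G04 E_nutans
chrom	label	type	Hbw	DY	GEM	KB	XN	NM	LJS	PJC	B05	H11	G04
1H	PeI I	PeI	+'	+'	+'	+'	+'	+'	+'	+''	+''	+''	+''
1H	PeI II	PeI	-	-	-	-	-	-	-	+'	+'	+'	+'
1St	RT (5H/1St)	RT	0	-	-	+	-	-	-	-	-	-	-
1St	De (1H514)	De	0	-	-	-	-	-	-	+	-	-	-
1Y	Du (2H558)	Du	-	-	-	-	-	-	-	-	-	-	+
2H	PaI I	PaI	+	-	-	-	-	-	-	-	-	-	-
2H	PeI I	PeI	+''	+'	+'	+'	+'	+'	+'	+''	+''	+''	+''
2H	PeI II	PeI	-	-	-	-	-	-	-	+'	+'	+'	+'
2H	RT (2H/2St)	RT	-	-	-	-	-	-	+	-	-	-	-
2St	PeI I	PeI	0	+'	+'	+'	+'	+'	+'	-	-	-	-
2St	RT (2H/2St)	RT	0	-	-	-	-	-	+	-	-	-	-
2St	RT (4H/2St)	RT	0	-	-	-	-	-	-	-	-	-	+
2Y	PeI III	PeI	0	0	0	0	0	0	0	+'	+'	+'	+'
3H	Du (3H448)	Du	-	-	-	-	-	-	-	+	+	-	+
3H	T (4H)	T	+	-	-	-	-	-	-	-	-	-	-
3H	RT (3H/6H)	RT	-	-	-	-	-	-	-	-	+	-	-
3H	PeI	PeI	-	+'	+'	+'	+'	+'	+'	-	-	-	-
3St	Du (3H448)	Du	-	-	-	-	-	-	-	-	+	+	+
3Y	De (3H287)	De	0	0	0	0	0	0	0	+	-	+	-
3Y	PaI	PaI	0	0	0	0	0	0	0	-	-	+	-
3Y	RT (4H/3Y)	RT	0	0	0	0	0	0	0	-	-	+	-
4H	Du (2L-1)	Du	-	-	-	-	-	-	-	-	+	-	+
4H	PeI I	PeI	+	-	-	-	-	-	-	+	-	-	-
4H	PeI II	PeI	-	+''	+''	+''	+''	+''	+''	-	-	-	-
4H	PeI III	PeI	-	-	-	-	+	-	-	-	-	-	-
4H	PeI IV	PeI	-	+	+	+	-	+	+	-	-	-	-
4H	PeI V	PeI	-	-	-	-	-	-	-	-	-	-	+
4H	PaI I	PaI	-	-	-	-	-	-	-	+''	+''	+''	+''
4H	RT (4H/6H)	RT	-	+'	+'	+'	+'	+'	+'	-	-	-	-
4H	RT (4H/3Y)	RT	-	-	-	-	-	-	-	-	-	+	-
4H	RT (4H/2St)	RT	-	-	-	-	-	-	-	-	-	-	+
4H	T (4H)	T	+	-	-	-	-	-	-	-	-	-	-
4St	PaI II	PaI	0	+'	+'	+'	+'	+'	+'	-	-	-	-
4Y	PeI VI	PeI	0	0	0	0	0	0	0	+'	+'	+'	+'
4Y	PeI VII	PeI	0	0	0	0	0	0	0	+'	+'	+'	+'
4Y	RT (4Y/5Y)	RT	0	0	0	0	0	0	0	+'	+'	+'	+'
5H	Du (1H514)	Du	+	-	-	-	-	-	-	-	-	-	-
5H	PaI I	PaI	+	-	-	-	-	-	-	-	-	-	-
5H	PaI II	PaI	+	-	-	-	-	-	-	-	-	-	-
5H	RT (5H/1St)	RT	-	-	-	+	-	-	-	-	-	-	-
5St	PeI I	PeI	0	+'	+'	+'	+'	+'	+'	-	-	-	-
5Y	PeI I	PeI	0	0	0	0	0	0	0	+'	+'	+'	+'
5Y	RT (4Y/5Y)	RT	0	0	0	0	0	0	0	+'	+'	+'	+'
5Y	PeI II	PeI	0	0	0	0	0	0	0	-	-	+	-
6H	PeI	PeI	-	+'	+'	+'	+'	+'	+'	+	-	+	-
6H	RT (4H/6H)	RT	-	+'	+'	+'	+'	+'	+'	-	-	-	-
6H	RT (3H/6H)	RT	-	-	-	-	-	-	-	-	+	-	-
7H	PaI	PaI	-	-	-	-	-	-	-	-	+	-	+
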