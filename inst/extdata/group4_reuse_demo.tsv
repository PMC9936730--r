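# Demonstration fixture (figure-derived, synthetic intervals): group-4
# rearrangement complexes with reference-interval endpoints arranged so the
# short-arm locus between probes 4H138 and 4H289 is hit by four independent
# complexes — the maximally reused pericentromeric breakpoint of group 4.
# Intervals are half-open marker slots on the group-4 reference order.
material	species	chrom	label	ref_start	ref_end
Hbw	H_bogdanii	4H	PeI I	2	5
DY	E_sibiricus	4H	PeI II	2	6
GEM	E_sibiricus	4H	PeI II	2	6
DY	E_sibiricus	4H	PeI IV	3	6
PJC	E_nutans	4Y	PeI VI	2	4
G04	E_nutans	4H	PeI V	0	2
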