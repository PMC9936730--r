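# Reference collinearity standard per homoeologous group: probe order from
# the short-arm telomere with the CEN token marking the centromere slot.
# Derived from probe_manifest.tsv (see its header for provenance).
group	item
1	1H077
1	1H102
1	1H230
1	1H305
1	CEN
1	1H356
1	1H411
1	1H468
1	1H490
1	1H514
2	2H095
2	2H151
2	2H240
2	CEN
2	2H288
2	2H339
2	2H450
2	2H558
2	2L-1
3	3H066
3	3H135
3	3H209
3	CEN
3	3H287
3	3H322
3	3H390
3	3H421
3	3H448
4	4H055
4	4H138
4	4H289
4	4H242
4	CEN
4	4H388
4	4H455
4	4H527
4	4H604
4	4L-6
5	5H112
5	5H167
5	5H201
5	CEN
5	5H362
5	5H470
5	5L-1
5	5H587
5	5H642
5	5H701
6	6H048
6	6H120
6	6H195
6	CEN
6	6H260
6	6H333
6	6H409
6	6H488
6	6H550
7	7H081
7	7H244
7	7H299
7	CEN
7	7H410
7	7H473
7	7H526
7	7H584
7	7H648
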