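# The four cDNA-library candidates discarded during probe development:
# each mapped too close to an already-selected probe to be discriminated
# by FISH pattern. Synthetic placeholder records (names and neighbours
# were not printed in the survey text).
probe_id	home_group	too_close_to	reason
1H096	1	1H102	indistinguishable FISH position
3H140	3	3H135	indistinguishable FISH position
5H475	5	5H470	indistinguishable FISH position
6H325	6	6H333	indistinguishable FISH position
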