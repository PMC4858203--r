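repeatId	description	X	Y	Z	L	lambda	escapeProb
SIMA	illustrative near-silent 500-bp interspersed homology (4H-7N_1-like)	4	7	1	500	0.08	0
SIMB	illustrative strongly mutated 500-bp interspersed homology (4H-7N_7-like)	4	7	7	500	10	0
SIMC	illustrative intermediate 500-bp interspersed homology (5H-6N_1-like)	5	6	1	500	3.6	0
SIMD	illustrative block-assisted level (5H-6N_1 + 15 bp-like)	5	6	1	500	9	0
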