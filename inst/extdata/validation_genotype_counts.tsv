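variant	genotype	affected	unaffected
chr17:800788G>A	AA	45	9
chr17:800788G>A	AR	11	56
chr17:800788G>A	RR	3	58
chr17:805276C>T	AA	45	10
chr17:805276C>T	AR	11	59
chr17:805276C>T	RR	3	58
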