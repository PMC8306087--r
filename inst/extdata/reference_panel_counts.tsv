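variant	gene	panel_hom_alt	panel_het	panel_hom_ref
chr17:805276C>T	TPO	6	15	701
chr17:743943T>C	SNTG2	4	16	615
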