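# Per-species gene counts for the RNase A domain family, the example of a
# mammalian-expanded RNA-binding domain: absent in invertebrates, rare in
# early vertebrates, expanded in mammals.
domain_id	celegans	dmelanogaster	drerio	xtropicalis	mmusculus	hsapiens
RNaseA	0	0	3	1	20	15
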