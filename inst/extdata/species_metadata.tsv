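# Six-species study panel: clade membership, neuron-count complexity proxy,
# and the distinct RNA-binding-domain family count of each repertoire.
species_id	display_name	clade	neuron_count	rbp_family_count
celegans	Caenorhabditis elegans	invertebrate	302	397
dmelanogaster	Drosophila melanogaster	invertebrate	200000	419
drerio	Danio rerio	vertebrate	10000000	455
xtropicalis	Xenopus tropicalis	vertebrate	16000000	446
mmusculus	Mus musculus	vertebrate	71000000	472
hsapiens	Homo sapiens	vertebrate	86000000000	469
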