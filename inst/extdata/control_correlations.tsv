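# Spearman correlations of family diversity vs neuron count for the RBP
# class and the three control protein classes on the six-species panel.
protein_class	rho	significant
RBP	0.886	yes
TF	0.845	yes
kinase	0.429	no
GPCR	-0.116	no
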