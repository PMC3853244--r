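drug_id	group	terms
D00225	Ion Channels	CHEBI:2611
D00293	Ion Channels	CHEBI:49575
D00300	G Protein-coupled Receptors	CHEBI:4636
D00311	Ion Channels	CHEBI:4858
D00430	Ion Channels	CHEBI:9073
D00494	G Protein-coupled Receptors	CHEBI:8461
D00506	Ion Channels	CHEBI:8069
D00549	Ion Channels	CHEBI:44915
D00669	G Protein-coupled Receptors	CHEBI:4637
D01177	G Protein-coupled Receptors	CHEBI:32091
D01205	G Protein-coupled Receptors	CHEBI:31472
D01310	Ion Channels	CHEBI:32124
D01372	Ion Channels	CHEBI:32315
D01485	G Protein-coupled Receptors	CHEBI:31981
D01657	Ion Channels	CHEBI:52993
D02419	G Protein-coupled Receptors	CHEBI:34720
D02624	Ion Channels	CHEBI:53760
D08283	Ion Channels	CHEBI:111762
D08473	G Protein-coupled Receptors	CHEBI:8802
D08690	Ion Channels	CHEBI:10125
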