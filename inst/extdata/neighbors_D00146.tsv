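drug_id	group	terms
D00089	G Protein-coupled Receptors	CHEBI:7872
D00101	G Protein-coupled Receptors	CHEBI:9937
D00176	G Protein-coupled Receptors	CHEBI:35940
D00284	G Protein-coupled Receptors	CHEBI:3901
D00291	G Protein-coupled Receptors	CHEBI:4450
D00410	Enzymes	CHEBI:44241
D00994	Enzymes	CHEBI:4759
D01002	G Protein-coupled Receptors	CHEBI:4025
D01163	G Protein-coupled Receptors	CHEBI:31554
D02783	G Protein-coupled Receptors	CHEBI:337298
D07431	G Protein-coupled Receptors	CHEBI:64628
D07759	G Protein-coupled Receptors	CHEBI:4024
D07905	G Protein-coupled Receptors	CHEBI:4822
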