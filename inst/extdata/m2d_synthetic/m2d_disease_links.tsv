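doid	mature_name	pubmed_id	target_genes
DOID:0001	sya-miR-1	11111111	GENE001,GENE002
DOID:0001	sya-miR-2	11111112	GENE003
DOID:0002	sya-miR-1	11111113	GENE004,GENE005
DOID:0002	syb-miR-1	11111114	GENE006
DOID:0003	syb-miR-2	11111115	GENE007
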