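Gene_name	Gene_id	Mutated	Organism	Motif	Len	Experiment_description	Matrix_id	Score
RBPA	ENSG0000000001	no	Mus_musculus	AAAA	4	RNAcompete	M001	1.0
RBPB	ENSG0000000002	yes	Homo_sapiens	MMMM	4	RNAcompete	M002	1.0
RBPC	ENSG0000000003	no	Homo_sapiens	CCCCC	5	SELEX	M003	1.0
RBPC	ENSG0000000003	no	Homo_sapiens	CCCCC	5	HTR-SELEX	M003	1.0
RBPD	ENSG0000000004	no	Homo_sapiens	UUUUU	5	RNAcompete	M005	1.0
RBPE	ENSG0000000005	no	Homo_sapiens	UUUUU	5	CLIP	M006	1.0
RBPF	ENSG0000000006	no	Homo_sapiens	NACGN	5	RNAcompete	M007	1.0
RBPG	ENSG0000000007	no	Homo_sapiens	NNNNNNN	7	RNAcompete	M008	1.0
RBPH	ENSG0000000008	no	Homo_sapiens	AAAAA	5	RNAcompete	M009	1.0
RBPI	ENSG0000000009	no	Homo_sapiens	GGGGGG	6	RNAcompete	M010	1.0
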