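block	term	total_genes	microarray	rnai	fusion	printed_p_fvm	printed_p_fvr
microarray_and_rnai	NRF2-mediated Oxidative Stress Response	180	13	12	24	0.041	0.026
microarray_and_rnai	p53 Signaling	98	8	11	18	0.028	0.113
microarray_and_rnai	Dme0048:Glutathione metabolism	50	18	8	22	0.271	0.002
microarray_and_rnai	Unfolded protein response	54	4	6	9	0.11	0.29
microarray_and_rnai	Glutathione Biosynthesis	3	1	3	3	0.04	1.00
rnai_and_fusion	hsa00230:Purine metabolism	153	ND	12	18	<0.01	0.17
rnai_and_fusion	hsa00240:Pyrimidine metabolism	95	ND	9	13	<0.01	0.24
rnai_and_fusion	EIF2 Signaling	185	ND	18	23	<0.01	0.25
rnai_and_fusion	REACT_71:Gene Expression	350	ND	54	60	<0.01	0.30
rnai_and_fusion	Salvage Pathways of Pyrimidine Ribonucleotides	93	ND	7	10	<0.01	0.31
rnai_and_fusion	Protein Ubiquitination Pathway	255	ND	20	23	<0.01	0.38
rnai_and_fusion	hsa03420:Nucleotide excision repair	44	ND	8	10	<0.01	0.39
rnai_and_fusion	hsa03010:Ribosome	87	ND	11	13	<0.01	0.41
rnai_and_fusion	REACT_1788:Transcription	131	ND	27	29	<0.01	0.50
rnai_and_fusion	P00023:General transcription regulation	38	ND	12	12	<0.01	0.50
rnai_and_fusion	REACT_1675:mRNA Processing	32	ND	13	13	<0.01	0.50
rnai_and_fusion	REACT_11045:Signaling by Wnt	61	ND	9	10	<0.01	0.50
rnai_and_fusion	P00045:Notch signaling pathway	50	ND	8	8	<0.01	0.50
rnai_and_fusion	Nucleotide Excision Repair Pathway	35	ND	9	10	<0.01	0.50
rnai_and_fusion	hsa03050:Proteasome	47	ND	8	9	<0.01	0.50
rnai_and_fusion	hsa03022:Basal transcription factors	35	ND	13	13	<0.01	0.50
rnai_and_fusion	Assembly of RNA Polymerase II Complex	50	ND	19	19	<0.01	0.50
rnai_and_fusion	gamma-glutamyl Cycle	15	ND	3	4	<0.01	0.50
rnai_and_fusion	REACT_383:DNA replication	97	ND	11	13	<0.01	0.50
microarray_and_fusion	Xenobiotic Metabolism Signaling	271	12	ND	21	0.07	<0.01
microarray_and_fusion	REACT_1698:Metabolism of nucleotides	77	6	ND	12	0.10	<0.01
microarray_and_fusion	PTEN Signaling	118	6	ND	11	0.15	<0.01
microarray_and_fusion	hsa00561:Glycerolipid metabolism	45	6	ND	9	0.29	<0.01
microarray_and_fusion	dme00980:Metabolism of xenobiotics by CYP450	64	23	ND	26	0.35	<0.01
microarray_and_fusion	dme00982:Drug metabolism	66	25	ND	28	0.36	<0.01
microarray_and_fusion	dme00040:Pentose and glucoronate interconversions	40	10	ND	12	0.40	<0.01
microarray_and_fusion	Lysine Degradation	5	2	ND	3	0.50	<0.01
microarray_and_fusion	PI3K/AKT Signaling	123	6	ND	12	0.11	<0.01
fusion_only	Amyloid Processing	51	ND	ND	7	<0.01	<0.01
fusion_only	REACT_13:Metabolism of amino acids	163	ND	ND	18	<0.01	<0.01
fusion_only	hsa00330:Arginine and Proline Metabolism	53	ND	ND	9	<0.01	<0.01
fusion_only	ERK/MAPK Signaling	187	ND	ND	18	<0.01	<0.01
fusion_only	PDGF Signaling	77	ND	ND	8	<0.01	<0.01
fusion_only	REACT_17015:Metabolism of proteins	217	ND	ND	25	<0.01	<0.01
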