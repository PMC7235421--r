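species	tissue	cell_type	gene_symbol	ref_count
human	Blood	T cell	CD3D	8
human	Blood	T cell	CD3E	10
human	Blood	T cell	CD3G	5
human	Blood	T cell	CD2	3
human	Blood	T cell	IL7R	4
human	Blood	T cell	TRAC	2
human	Blood	B cell	CD19	9
human	Blood	B cell	MS4A1	7
human	Blood	B cell	CD79A	6
human	Blood	B cell	CD79B	4
human	Blood	B cell	IGHM	2
human	Blood	Natural killer cell	NKG7	6
human	Blood	Natural killer cell	GNLY	7
human	Blood	Natural killer cell	KLRD1	4
human	Blood	Natural killer cell	NCAM1	5
human	Blood	Natural killer cell	KLRF1	2
human	Blood	Monocyte	CD14	9
human	Blood	Monocyte	LYZ	6
human	Blood	Monocyte	FCN1	3
human	Blood	Monocyte	S100A8	4
human	Blood	Monocyte	S100A9	4
human	Blood	Monocyte	FCGR3A	3
human	Blood	Macrophage	CD68	8
human	Blood	Macrophage	CD163	6
human	Blood	Macrophage	LYZ	3
human	Blood	Macrophage	FCGR3A	2
human	Blood	Macrophage	MRC1	4
human	Blood	Megakaryocyte	PPBP	5
human	Blood	Megakaryocyte	PF4	6
human	Blood	Megakaryocyte	ITGA2B	3
human	Blood	Megakaryocyte	GP9	2
human	Blood	Dendritic cell	FCER1A	4
human	Blood	Dendritic cell	CST3	3
human	Blood	Dendritic cell	CLEC9A	2
human	Blood	Dendritic cell	ITGAX	3
human	Brain	Neuron	RBFOX3	7
human	Brain	Neuron	MAP2	5
human	Brain	Neuron	SYP	4
human	Brain	Astrocyte	GFAP	9
human	Brain	Astrocyte	AQP4	6
human	Brain	Astrocyte	SLC1A3	3
human	Blood	Endothelial cell	PECAM1	8
human	Blood	Endothelial cell	VWF	7
human	Blood	Endothelial cell	CDH5	4
human	Blood	Mesenchymal stem cell	ENG	4
human	Blood	Mesenchymal stem cell	THY1	5
human	Blood	Mesenchymal stem cell	NT5E	3
human	Blood	Mesenchymal stem cell	COL1A1	2
mouse	Blood	T cell	CD3E	6
mouse	Blood	T cell	CD3D	4
mouse	Blood	B cell	CD19	5
mouse	Blood	B cell	MS4A1	3
mouse	Blood	Monocyte	LYZ2	4
mouse	Blood	Monocyte	CD14	3
mouse	Blood	Natural killer cell	NKG7	3
mouse	Blood	Natural killer cell	KLRB1C	2
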