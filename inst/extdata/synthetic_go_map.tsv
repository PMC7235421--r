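CD19	GO:0042113	B cell activation
MS4A1	GO:0042113	B cell activation
CD79A	GO:0042113	B cell activation
CD79B	GO:0042113	B cell activation
CD3D	GO:0042110	T cell activation
CD3E	GO:0042110	T cell activation
CD3G	GO:0042110	T cell activation
IL7R	GO:0042110	T cell activation
CD2	GO:0042110	T cell activation
NKG7	GO:0001906	cell killing
GNLY	GO:0001906	cell killing
KLRD1	GO:0001906	cell killing
PPBP	GO:0030168	platelet activation
PF4	GO:0030168	platelet activation
ITGA2B	GO:0030168	platelet activation
GP9	GO:0030168	platelet activation
CD14	GO:0006954	inflammatory response
LYZ	GO:0006954	inflammatory response
S100A8	GO:0006954	inflammatory response
S100A9	GO:0006954	inflammatory response
FCN1	GO:0006954	inflammatory response
CD68	GO:0006909	phagocytosis
CD163	GO:0006909	phagocytosis
MRC1	GO:0006909	phagocytosis
PECAM1	GO:0001525	angiogenesis
VWF	GO:0001525	angiogenesis
CDH5	GO:0001525	angiogenesis
COL1A1	GO:0030198	extracellular matrix organization
ENG	GO:0030198	extracellular matrix organization
NT5E	GO:0030198	extracellular matrix organization
THY1	GO:0030198	extracellular matrix organization
GFAP	GO:0007399	nervous system development
AQP4	GO:0007399	nervous system development
SLC1A3	GO:0007399	nervous system development
RBFOX3	GO:0007399	nervous system development
MAP2	GO:0007399	nervous system development
SYP	GO:0007399	nervous system development
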