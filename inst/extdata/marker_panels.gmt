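pre_OPC	pre-OPC specification markers	ASCL1	BTG2	HES6	DLL1	DLL3
OPC	oligodendrocyte progenitor cell markers	PDGFRA	CSPG4	PCDH15	PTPRZ1
COP	differentiation-committed oligodendrocyte precursor markers	NEU4	SOX6	VCAN
astrocyte	astrocyte markers	ALDOC	AQP4	CLU	GFAP	MLC1	S100B	SLC1A2
APC	astrocyte precursor cell markers	FABP7	FGFR3	SLC1A3
oligodendrocyte	mature oligodendrocyte / myelin markers	MOBP	MBP	MOG	KLK6
T_cell	T lymphocyte markers	CD2	CD3D	CD3E	CD3G
microglia	microglia markers	CX3CR1	P2RY12	TMEM119
macrophage	macrophage markers	CD163	S100A8	S100A9	AIF1
proliferation	cell-cycle markers, concomitant detection defines proliferating cells	MKI67	TOP2A	CCNB2	CDK1
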