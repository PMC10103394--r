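EM	synthetic EM module signature: canonical anchors plus simulated filler genes	NFIA	SOX9	POU3F2	EGFR	SYNEM01	SYNEM02	SYNEM03	SYNEM04	SYNEM05	SYNEM06	SYNEM07	SYNEM08	SYNEM09	SYNEM10	SYNEM11	SYNEM12
PM	synthetic PM module signature: canonical anchors plus simulated filler genes	CHD7	MYT1	OLIG1	OLIG2	PDGFRA	SOX4	SOX6	SOX8	SYNPM01	SYNPM02	SYNPM03	SYNPM04	SYNPM05	SYNPM06	SYNPM07	SYNPM08	SYNPM09	SYNPM10	SYNPM11	SYNPM12
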