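role	node
source	MET_melan
source	EDNRB_melan
source	EGFR_kerat
source	PTGER1_melan
source	PTGER2_kerat
source	PTGER3_melan
source	PTGER4_kerat
source	FAS_kerat
source	FZD3_melan
source	CSF2RA_melan
source	IL1R1_kerat
source	IL6R_kerat
source	KIT_melan
source	MC1R_kerat
source	MC1R_melan
source	F2RL1_kerat
source	TNFRSF1A_kerat
source	NTRK1_melan
source	UVA
source	UVB
target	Eumelanin_melan
target	Pheomelanin_melan
target	Dendrite_formation_melan
target	Melanosome_phagocytosis_kerat
target	Apoptosis_melan
target	Cell_proliferation_melan
target	Melanosome_biogenesis
target	Cell_survival_melan
target	Cell_cycle_arrest_melan
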