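table	process	role	perturbed	path
3	UV mediated melanogenesis (tyrosinase activation)	predicted	NA	UV- > Singlet_oxygen_kerat- > Ceramide_kerat- > PLA2_kerat- > Arachidonic_Acid_kerat- > PGE2_kerat- > PTGER3_melan- > PLC_melan- > DAG_melan- > PRKCB_melan- > TYR_melan- > Eumelanin_melan
3	UV mediated melanogenesis (tyrosinase activation)	predicted	NA	UV- > Singlet_oxygen_kerat- > Ceramide_kerat- > PLA2_kerat- > Arachidonic_Acid_kerat- > PGE2_kerat- > PTGER3_melan- > PLC_melan- > DAG_melan- > PRKCB_melan- > TYR_melan- > Pheomelanin_melan
3	UV mediated melanogenesis (tyrosinase activation)	predicted	NA	UV- > Singlet_oxygen_kerat- > Ceramide_kerat- > PRKCZ_kerat- > NFKB1_kerat- > PTGS2_kerat
3	UV mediated melanogenesis (tyrosinase expression)	predicted	NA	UV- > Singlet_oxygen_kerat- > Ceramide_kerat- > PRKCZ_kerat- > NFKB1_kerat- > KITLG_kerat- > KIT_melan- > PIK3CA_melan- > PDPK1_melan- > AKT1_melan- > CREB1_melan- > MITF_melan- > TYR_melan- > Eumelanin_melan
3	UV mediated melanogenesis (tyrosinase expression)	predicted	NA	UV- > Singlet_oxygen_kerat- > Ceramide_kerat- > PRKCZ_kerat- > NFKB1_kerat- > KITLG_kerat- > KIT_melan- > PIK3CA_melan- > PDPK1_melan- > AKT1_melan- > CREB1_melan- > MITF_melan- > TYR_melan- > Pheomelanin_melan
3	UV mediated melanogenesis (tyrosinase expression)	predicted	NA	UVA- > Singlet_oxygen_kerat- > Ceramide_kerat- > PRKCZ_kerat- > NFKB1_kerat- > NOS2_kerat- > Nitric_oxide_kerat- > GUCY1A2_melan- > cGMP_melan- > PRKG1_melan- > CREB1_melan- > MITF_melan- > TYR_melan- > melanogenesis
3	UV mediated alpha MSH production	predicted	NA	UVA- > Lipid_Peroxidation_kerat- > 4HNE_kerat- > DNA_Damage_kerat- > TP53_kerat- > alpha_MSH_kerat
3	UV mediated melanocyte dendrite formation	predicted	NA	UV- > Singlet_oxygen_kerat- > Ceramide_kerat- > PRKCZ_kerat- > NFKB1_kerat- > KITLG_kerat- > KIT_melan- > PIK3CA_melan- > RAC1_melan- > RAC1:PARD6A:CDC42_melan- > PRKCZ_melan- > Dendrite_formation_melan
3	UV mediated NFKB1 activation and secretion of paracrine factors	predicted	NA	UV- > Singlet_oxygen_kerat- > Ceramide_kerat- > PRKCZ_kerat- > NFKB1_kerat- > EDN1_kerat
3	UV mediated NFKB1 activation and secretion of paracrine factors	predicted	NA	UV- > Singlet_oxygen_kerat- > Ceramide_kerat- > PRKCZ_kerat- > NFKB1_kerat- > CSF2_kerat
3	UV mediated NFKB1 activation and secretion of paracrine factors	predicted	NA	UV- > Singlet_oxygen_kerat- > Ceramide_kerat- > PRKCZ_kerat- > NFKB1_kerat- > KITLG_kerat
3	UV mediated melanocyte proliferation	predicted	NA	UVA- > Singlet_oxygen_kerat- > Ceramide_kerat- > PRKCZ_kerat- > NFKB1_kerat- > CSF2_kerat- > CSF2RA_melan- > CSF2RA:JAK1_melan- > STAT3_melan- > CCND1_melan- > CDK4:CCND1_melan- > Cell_proliferation_melan
3	UV induced melanosome phagocytosis	predicted	NA	UVA- > Singlet_oxygen_kerat- > Ceramide_kerat- > PRKCZ_kerat- > NFKB1_kerat- > F2RL1_kerat- > RHOA_kerat- > Melanosome_phagocytosis_kerat
5	UV induced melanin synthesis	control	PTGER3_melan	UV- > Singlet_oxygen_kerat- > Ceramide_kerat- > PLA2_kerat- > Arachidonic_Acid_kerat- > PGE2_kerat- > PTGER3_melan- > PLC_melan- > DAG_melan- > PRKCB_melan- > TYR_melan- > Melanogensis
5	UV induced melanin synthesis	alternate	PTGER3_melan	UV- > Singlet_oxygen_kerat- > Ceramide_kerat- > PRKCZ_kerat- > NFKB1_kerat- > EDN1_kerat- > EDNRB_melan- > PLC_melan- > DAG_melan- > PRKCB_melan- > TYR_melan- > Eumelanin_melan
5	UV induced melanin synthesis	control	TYR_melan	UV- > Singlet_oxygen_kerat- > Ceramide_kerat- > PLA2_kerat- > Arachidonic_Acid_kerat- > PGE2_kerat- > PTGER3_melan- > PLC_melan- > DAG_melan- > PRKCB_melan- > TYR_melan- > Melanogensis
5	UV induced melanin synthesis	alternate	TYR_melan	None
5	UV induced dendrite formation	control	KIT_melan	UV- > Singlet_oxygen_kerat- > Ceramide_kerat- > PRKCZ_kerat- > NFKB1_kerat- > KITLG_kerat- > KIT_melan- > PIK3CA_melan- > RAC1_melan- > RAC1:PARD6A:CDC42_melan- > PRKCZ_melan- > Dendrite_formation_melan
5	UV induced dendrite formation	alternate	KIT_melan	UVB- > Lipid_Peroxidation_kerat- > 4HNE_kerat- > DNA_Damage_kerat- > TP53_kerat- > ACTH_kerat- > MC1R_melan- > ADCY4_melan- > cAMP_melan- > RAP1A_melan- > RAC1_melan- > RAC1:PARD6A:CDC42_melan- > PRKCZ_melan- > Dendrite_formation_melan
5	UV induced melanosome phagocytosis	control	F2RL1_kerat	UV- > Singlet_oxygen_kerat- > Ceramide_kerat- > PRKCZ_kerat- > NFKB1_kerat- > F2RL1_kerat- > RHOA_kerat- > Melanosome_phagocytosis_kerat
5	UV induced melanosome phagocytosis	alternate	F2RL1_kerat	None
5	UV induced melanocyte proliferation	control	NFKB1_kerat	UV- > Singlet_oxygen_kerat- > Ceramide_kerat- > PRKCZ_kerat- > NFKB1_kerat- > CSF2_kerat- > CSF2RA_melan- > CSF2RA:JAK1_melan- > STAT3_melan- > CCND1_melan- > CDK4:CCND1_melan- > Cell_proliferation_melan
5	UV induced melanocyte proliferation	alternate	NFKB1_kerat	UVB- > Lipid_Peroxidation_kerat- > 4HNE_kerat- > DNA_Damage_kerat- > TP53_kerat- > ACTH_kerat- > MC1R_melan- > ADCY4_melan- > cAMP_melan- > PRKACA_melan- > CREB1_melan- > MITF_melan- > CDK4_melan- > CDK4:CCND1_melan- > Cell_proliferation_melan
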