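accession	name	family	tf_class	superclass	specificity
IPR000005	Helix-turn-helix, AraC type	Helix-turn-helix, AraC type	HTH-AraC	HTH-AraC	bacterial/archaeal/viral
IPR000007	Tubby, C-terminal	Tubby TF	Tubby	Tubby	pan-eukaryotic
IPR000197	Zinc finger, TAZ-type	zf-TAZ	zf-TAZ	zf-TAZ	pan-eukaryotic
IPR000232	Heat shock factor (HSF)-type, DNA-binding	Heat shock factor (HSF)-type	HSF	HSF	pan-eukaryotic
IPR000327	POU-specific	lambda repressor-like/POU	POU	HTH	metazoan
IPR000418	Ets	Ets	Ets	Ets	metazoan
IPR000551	Bacterial regulatory protein, MerR	Bacterial regulatory protein, MerR	MerR	MerR	bacterial/archaeal/viral
IPR000571	Zinc finger CCCH-type	C2H2/CCHC/CCCH	C2H2-like ZF	C2H2-like ZF	pan-eukaryotic
IPR000679	Zinc finger, GATA-type	GATA	GATA	GATA	pan-eukaryotic
IPR000792	Bacterial regulatory protein, LuxR	Bacterial regulatory protein, LuxR	LuxR	LuxR	bacterial/archaeal/viral
IPR000814	TATA-box binding	TATA-box binding	TBP	TBP	pan-eukaryotic
IPR000818	TEA/ATTS	TEA/ATTS	TEA	TEA	pan-eukaryotic
IPR000835	Bacterial regulatory protein, MarR	Bacterial regulatory protein, MarR	MarR	MarR	bacterial/archaeal/viral
IPR000843	Bacterial regulatory protein, LacI	Bacterial regulatory protein, LacI	LacI	LacI	bacterial/archaeal/viral
IPR000944	Transcriptional regulator, Rrf2	Rrf2	Rrf2	Rrf2	bacterial/archaeal/viral
IPR000967	Zinc finger, NF-X1-type	Zn-finger, NF-X1 type	NF-X1	NF-X1	pan-eukaryotic
IPR001034	Bacterial regulatory protein, DeoR N-terminal	Bacterial regulatory protein, DeoR N-terminal	DeoR	DeoR	bacterial/archaeal/viral
IPR001083	Copper fist DNA-binding	Copper fist	Copper-fist	Copper-fist	fungal
IPR001138	Zn2 Cys6 Zn_cluster	Zn cluster	Zn-cluster	Zn-cluster	fungal
IPR001275	DM DNA-binding	DM DNA-binding	DM	DM	metazoan
IPR001289	CCAAT-binding TF, subunit B	CCAAT-BindingTF	CCAAT	CCAAT	pan-eukaryotic
IPR001356	Homeobox	HTH/Homeodomain-like	HD	HTH	pan-eukaryotic
IPR001387	Helix-turn-helix type 3	Helix-turn-helix type 3	HTH-3	HTH-3	bacterial/archaeal/viral
IPR001471	Pathogenesis-related TF and ERF, DBD	Pathogenesis-related TF and ERF	AP2/ERF	AP2/ERF	plant
IPR001523	Paired box protein, N-terminal	Paired box	Paired-box	Paired-box	metazoan
IPR001628	Zinc finger, nuclear hormone receptor-type	GR-like	GR-like	GR-like	metazoan
IPR001699	Transcription factor, T-box	T-box	T-box	T-box	metazoan
IPR001766	Fork head transcription factor	Fork head TF	Fork-head	Fork-head	pan-eukaryotic
IPR001808	Bacterial regulatory protein, Crp	Bacterial regulatory protein, Crp	Crp	Crp	bacterial/archaeal/viral
IPR001845	Bacterial regulatory protein, ArsR	Bacterial regulatory protein, ArsR	ArsR	ArsR	bacterial/archaeal/viral
IPR001878	Zinc finger, CCHC-type	C2H2/CCHC/CCCH	C2H2-like ZF	C2H2-like ZF	pan-eukaryotic
IPR002059	Cold-shock protein, DNA-binding	Cold-shock DBD	Cold-shock	Cold-shock	pan-eukaryotic
IPR002100	Transcription factor, MADS-box	MADS-box/SRF	MADS	MADS	pan-eukaryotic
IPR002197	Helix-turn-helix, Fis-type	Helix-turn-helix, Fis-type	Fis	Fis	bacterial/archaeal/viral
IPR002653	Zinc finger, A20-type	zf-A20	zf-A20	zf-A20	pan-eukaryotic
IPR003150	DNA-binding RFX	RFX_DNA_binding	RFX	RFX	pan-eukaryotic
IPR003163	APSES-type DNA-binding domain	APSES	APSES	APSES	fungal
IPR003316	E2F/dimerisation partner (TDP)	E2F_TDP	E2F	E2F	pan-eukaryotic
IPR003350	Homeodomain CUT	CUT	CUT	HTH	metazoan
IPR003656	Zinc finger, BED-type predicted	zf-BED	zf-BED	zf-BED	pan-eukaryotic
IPR003657	DNA-binding WRKY	DNA-binding WRKY	WRKY	WRKY	plant
IPR003902	Transcriptional regulator, GCM-like	GCM-like	GCM	GCM	metazoan
IPR003958	TF CBF/NF-Y/archaeal histone	CBF/NF-Y/archaeal histone	CBF/NF-Y	CBF/NF-Y	pan-eukaryotic
IPR004022	DDT	DDT	DDT	DDT	pan-eukaryotic
IPR004181	Zinc finger, MIZ-type	zf-MIZ	zf-MIZ	zf-MIZ	pan-eukaryotic
IPR004198	Zinc finger, C5HC2-type	zf-C5HC2	C5HC2-ZF	C5HC2-ZF	pan-eukaryotic
IPR004333	Transcription factor, SBP-box	SBP-box	SBP	SBP	plant
IPR004645	DNA-binding protein Tfx	DNA-binding protein Tfx	Tfx	Tfx	bacterial/archaeal/viral
IPR004823	TATA box binding protein associated factor (TAF)	TATA box binding protein associated factor (TAF)	TAF	TAF	pan-eukaryotic
IPR004826	Maf transcription factor	Maf TF	Maf	Maf	metazoan
IPR004827	Basic-leucine zipper (bZIP) TF	bZIP	bZIP	bZIP	pan-eukaryotic
IPR005011	SART-1 protein	SART-1	SART-1	SART-1	pan-eukaryotic
IPR006780	YABBY protein	YABBY	YABBY	YABBY	plant
IPR006856	Mating-type protein MAT alpha 1	Mating-type protein MATalpha1	MATalpha1	MATalpha1	fungal
IPR007087	Zinc finger, C2H2-type	C2H2/CCHC/CCCH	C2H2-like ZF	C2H2-like ZF	pan-eukaryotic
IPR007196	CCR4-Not complex component, Not1	CCR4-Not complex component, Not1	Not1	Not1	pan-eukaryotic
IPR007396	Negative transcriptional regulator	Negative transcriptional regulator	NegTR	NegTR	other
IPR007604	CP2 transcription factor	CP2 TF	CP2	CP2	metazoan
IPR007889	Helix-turn-helix, Psq	Helix-turn-helix, Psq	Psq	Psq	metazoan
IPR008895	YL1 nuclear	YL1	YL1	YL1	pan-eukaryotic
IPR008917	Eukaryotic transcription factor, Skn-1-like	Skn-1	Skn-1	Skn-1	pan-eukaryotic
IPR008967	p53-like transcription factor, DNA-binding	p53	p53	p53	metazoan
IPR009044	ssDNA-binding transcriptional regulator	ssDNA-binding transcriptional regulator	ssDNA-TR	ssDNA-TR	other
IPR009057	Homeodomain-like	HTH/Homeodomain-like	HD	HTH	pan-eukaryotic
IPR009061	Putative DNA binding	Putative DNA binding	PutDB	PutDB	other
IPR009395	GCN5-like 1	GCN5L1	GCN5L1	GCN5L1	pan-eukaryotic
IPR010666	Zinc finger, GRF-type	zf-GRF	zf-GRF	zf-GRF	pan-eukaryotic
IPR010770	SGT1	SGT1	SGT1	SGT1	pan-eukaryotic
IPR010919	SAND-like	SAND-like	SAND	SAND	pan-eukaryotic
IPR010921	Trp repressor/replication initiator	Trp repressor/replication initiator	TrpR	TrpR	bacterial/archaeal/viral
IPR010982	Lambda repressor-like, DNA-binding	lambda repressor-like/POU	lambda-repressor-like	HTH	bacterial/archaeal/viral
IPR010985	Ribbon-helix-helix	Ribbon-helix-helix	RHH	RHH	bacterial/archaeal/viral
IPR011598	Helix-loop-helix DNA-binding	HLH	HLH	HLH	pan-eukaryotic
IPR012294	Transcription factor TFIID, C-terminal	TFIID	TFIID	TFIID	pan-eukaryotic
IPR013921	TATA-binding related factor	TATA-binding related factor	TRF	TRF	pan-eukaryotic
IPR013932	TATA-binding protein interacting (TIP20)	TATA-binding protein interacting (TIP20)	TIP20	TIP20	pan-eukaryotic
IPR015988	STAT transcription factor, coiled coil	STAT	STAT	STAT	metazoan
IPR016032	Signal transduction response regulator, C-term. effector	Signal transduction response regulator, C-term.	RR-effector	RR-effector	bacterial/archaeal/viral
IPR016177	DNA-binding, integrase-type	DNA-binding, integrase-type	Integrase-DB	Integrase-DB	other
IPR024061	NDT80 DNA-binding domain	NDT80	NDT80	NDT80	pan-eukaryotic
IPR025659	Tubby C-terminal-like domain	Tubby TF	Tubby	Tubby	pan-eukaryotic
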