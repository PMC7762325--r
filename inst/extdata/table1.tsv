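patient_id	analysis_id	primary_status	gender	age	localization	sample_type	diagnosis	grade	atrx	tert	h3	egfr_amp	seven_plus_ten_minus	other_drivers	molecular_subset
NOT-0046	NOT-0046_TA	primary	M	31	thalamic	FFPE	Glioblastoma, IDH wild-type	IV	MUT	WT	WT	amplification	FALSE		mGBM
	NOT-0046_TB	recurrent	M	31	thalamic	LiN2	Glioblastoma, IDH wild-type	IV	MUT	WT	WT	amplification	TRUE		mGBM
NOT-0047	NOT-0047	recurrent	M	49	parietal	LiN2	Glioblastoma, IDH wild-type	IV	WT	WT	WT	amplification	TRUE		mGBM
NOT-0048	NOT-0048	primary	F	45	frontal	LiN2	Glioblastoma, IDH wild-type	IV	WT	WT	WT	amplification	TRUE		mGBM
NOT-0051	NOT-0051	primary	M	48	temporal	FFPE	Glioblastoma, IDH wild-type	IV	WT	C228	WT	amplification	TRUE		mGBM
NOT-0052	NOT-0052	primary	F	65	hippocampus	FFPE	Anaplastic astrocytoma, IDH wild-type	III	WT	C228	WT	amplification	TRUE		mGBM
NOT-0054	NOT-0054	recurrent	F	40	frontal	LiN2	Glioblastoma, IDH wild-type	IV	WT	C250	WT	amplification	TRUE		mGBM
NOT-0056	NOT-0056	primary	F	67	hippocampus	LiN2	Glioblastoma, IDH wild-type	IV	WT	C228	WT	amplification	TRUE		mGBM
NOT-0057	NOT-0057	primary	F	62	temporal	LiN2	Glioblastoma, IDH wild-type	IV	WT	C228	WT	amplification	TRUE		mGBM
NOT-0058	NOT-0058	primary	F	71	frontal	FFPE	Glioblastoma, IDH wild-type	IV	WT	C228	WT	amplification	TRUE		mGBM
NOT-0060	NOT-0060	primary	M	48	hippocampus	FFPE	Glioblastoma, IDH wild-type	IV	WT	C250	WT	amplification	TRUE		mGBM
NOT-0061	NOT-0061	primary	M	55	occipital	FFPE	Glioblastoma, IDH wild-type	IV	WT	C250	WT	copy neutral	FALSE		mGBM
NOT-0062	NOT-0062	primary	M	66	frontal	FFPE	Glioblastoma, IDH wild-type	IV	WT	C250	WT	amplification	TRUE		mGBM
NOT-0064	NOT-0064	primary	F	48	frontal	LiN2	Glioblastoma, IDH wild-type	IV	WT	C228	WT	amplification	TRUE		mGBM
NOT-0065	NOT-0065	primary	M	59	occipital	LiN2	Glioblastoma, IDH wild-type	IV	WT	C228	WT	amplification	FALSE		mGBM
NOT-0066	NOT-0066	primary	F	69	frontal	LiN2	Glioblastoma, IDH wild-type	IV	WT	C228	WT	amplification	TRUE		mGBM
NOT-0067	NOT-0067	primary	F	51	parietal	LiN2	Glioblastoma, IDH wild-type	IV	WT	WT	WT	amplification	TRUE		mGBM
NOT-0069	NOT-0069_TA	primary	M	46	parietal	FFPE	Glioblastoma, IDH wild-type	IV	WT	C228	WT	amplification	TRUE		mGBM
	NOT-0069_TB	recurrent	M	46	parietal	LiN2	Glioblastoma, IDH wild-type	IV	WT	C228	WT	amplification	TRUE		mGBM
NOT-0070	NOT-0070	primary	M	46	temporal	FFPE	Glioblastoma, IDH wild-type	IV	WT	C250	WT	copy neutral	TRUE		mGBM
NOT-0071	NOT-0071	primary	M	47	multifocal	LiN2	Glioblastoma, IDH wild-type	IV	WT	WT	WT	amplification	FALSE		mGBM
NOT-0073	NOT-0073	primary	M	51	frontal	LiN2	Glioblastoma, IDH wild-type	IV	WT	C228	WT	amplification	TRUE		mGBM
NOT-0076	NOT-0076	primary	M	51	thalamus	LiN2	Glioblastoma, IDH wild-type	IV	WT	C228	WT	amplification	TRUE		mGBM
NOT-0078	NOT-0078	primary	F	52	frontal	LiN2	Diffuse astrocytoma, WHO grade II, IDH wild-type	II	MUT	WT	WT	amplification	FALSE		mGBM
NOT-0079	NOT-0079	primary	M	40	parietal	LiN2	Glioblastoma, IDH wild-type	IV	WT	C228	WT	amplification	TRUE		mGBM
NOT-0082	NOT-0082	primary	M	68	gliomatosis	FFPE	Anaplastic astrocytoma, WHO grade III, IDH wild-type	III	WT	C228	WT	amplification	FALSE		mGBM
NOT-0084	NOT-0084	primary	M	54	parietal	LiN2	Glioblastoma, IDH wild-type	IV	WT	WT	WT	amplification	FALSE		mGBM
NOT-0085	NOT-0085	primary	M	59	frontal	LiN2	Glioblastoma, IDH wild-type	IV	WT	C250	WT	amplification	TRUE		mGBM
NOT-0086	NOT-0086	primary	M	53	temporal	FFPE	Glioblastoma, IDH wild-type	IV	WT	C250	WT	amplification	TRUE		mGBM
NOT-0087	NOT-0087	primary	M	63	frontal	FFPE	Glioblastoma, IDH wild-type	IV	WT	C250	WT	amplification	TRUE		mGBM
NOT-0089	NOT-0089	primary	M	62	parietal	LiN2	Glioblastoma, IDH wild-type	IV	WT	C228	WT	copy neutral	FALSE		mGBM
NOT-0091	NOT-0091	primary	F	48	frontal	FFPE	Glioblastoma, IDH wild-type	IV	WT	C228	WT	amplification	TRUE		mGBM
NOT-0092	NOT-0092_TA	primary	M	51	frontal	LiN2	Glioblastoma, IDH wild-type	IV	WT	WT	WT	amplification	FALSE		mGBM
	NOT-0092_TB	recurrent	M	51	frontal	FFPE	Glioblastoma, IDH wild-type	IV	WT	WT	WT	amplification	FALSE		mGBM
NOT-0094	NOT-0094	primary	M	64	frontal	FFPE	Glioblastoma, IDH wild-type	IV	WT	C228	WT	amplification	TRUE		mGBM
NOT-0075	NOT-0075_TA	primary	F	49	cerebellar	LiN2	Anaplastic astrocytoma, IDH wild-type	III	MUT	WT	WT	amplification	TRUE		mGBM
	NOT-0075_TB	recurrent	F	49	cerebellar	LiN2	Glioblastoma, IDH wild-type	IV	MUT	WT	WT	copy neutral	FALSE		mGBM
NOT-0059	NOT-0059	primary	F	76	frontal	FFPE	Glioblastoma, IDH wild-type	IV	WT	WT	WT	copy neutral	FALSE	SETD2 (Y2523)	Others
NOT-0063	NOT-0063	primary	M	37	gliomatosis	LiN2	Glioblastoma, IDH wild-type	IV	MUT	WT	G34R	copy neutral	FALSE		Others
NOT-0068	NOT-0068	primary	M	64	gliomatosis	LiN2	Diffuse astrocytoma, IDH wild-type	II	MUT	WT	WT	copy neutral	FALSE	SETD2 (A2553T)	Others
NOT-0083	NOT-0083	primary	F	41	corpus callosum	FFPE	Glioblastoma, IDH wild-type	IV	MUT	WT	WT	copy neutral	FALSE	SETD2 (R2040*; R2510H)	Others
NOT-0088	NOT-0088_TA	primary	F	34	cerebellar	LiN2	Anaplastic astrocytoma with piloid features, IDH wild-type	III	WT	WT	WT	copy neutral	TRUE	FGFR1 (K567E; V742M)	Others
	NOT-0088_TB	recurrent	F	34	cerebellar	LiN2	Glioblastoma, IDH wild-type	IV	WT	WT	WT	copy neutral	FALSE	FGFR1 (K567E; V742M)	Others
NOT-0090	NOT-0090_TA	primary	M	28	frontal	LiN2	Glioblastoma, IDH wild-type	IV	MUT	WT	WT	copy neutral	FALSE	SETD2 (KQ583fs)	Others
	NOT-0090_TB	recurrent	M	28	frontal	LiN2	Glioblastoma, IDH wild-type	IV	MUT	WT	WT	copy neutral	FALSE		Others
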