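concept_id	type	preferred_label	synonym
serpina3	PROTEIN_OR_MRNA	SERPINA3	Alpha 1-antichymotrypsin
serpina3	PROTEIN_OR_MRNA	SERPINA3	serpin peptidase inhibitor clade A
serpina3	PROTEIN_OR_MRNA	SERPINA3	AACT
serpina3	PROTEIN_OR_MRNA	SERPINA3	ACT
app	PROTEIN_OR_MRNA	APP	Amyloid beta A4 precursor protein
app	PROTEIN_OR_MRNA	APP	AD1
app	PROTEIN_OR_MRNA	APP	ABETA
app	PROTEIN_OR_MRNA	APP	amyloid beta A4 protein
app	PROTEIN_OR_MRNA	APP	amyloid precursor protein
apod	PROTEIN_OR_MRNA	APOD	Apolipoprotein D
apoe	PROTEIN_OR_MRNA	apoE	Apolipoprotein E
apoe	PROTEIN_OR_MRNA	apoE	APOE
apoe	PROTEIN_OR_MRNA	apoE	AD2
bcl2	PROTEIN_OR_MRNA	BCL2	B-cell leukemia lymphoma 2
bace1	PROTEIN_OR_MRNA	BACE1	Beta-site APP-Cleaving Enzyme 1
bace1	PROTEIN_OR_MRNA	BACE1	BACE-1
bche	PROTEIN_OR_MRNA	BCHE	Butyrylcholinesterase
crp	PROTEIN_OR_MRNA	CRP	C-reactive protein
crp	PROTEIN_OR_MRNA	CRP	pentraxin-related protein
chat	PROTEIN_OR_MRNA	CHAT	Choline Acetyltransferase
chat	PROTEIN_OR_MRNA	CHAT	ChAt
chat	PROTEIN_OR_MRNA	CHAT	CHOACTase
clu	PROTEIN_OR_MRNA	CLU	Clusterin
clu	PROTEIN_OR_MRNA	CLU	APOJ
clu	PROTEIN_OR_MRNA	CLU	Apolipoprotein J
c1qb	PROTEIN_OR_MRNA	C1QB	Complement component 1 q subcomponent beta polypeptide
esr1	PROTEIN_OR_MRNA	ESR1	Estrogen Receptor 1
esr1	PROTEIN_OR_MRNA	ESR1	estrogen receptor alpha
gfap	PROTEIN_OR_MRNA	GFAP	Glial fibrillary acidic protein
hspa5	PROTEIN_OR_MRNA	HSPA5	Heat shock 70kD protein 5
hspa5	PROTEIN_OR_MRNA	HSPA5	glucose-regulated protein 78
il1b	PROTEIN_OR_MRNA	IL1B	Interleukin 1 beta
il1b	PROTEIN_OR_MRNA	IL1B	IL-1beta
il6	PROTEIN_OR_MRNA	IL6	Interleukin 6
il6	PROTEIN_OR_MRNA	IL6	IFNB2
il6	PROTEIN_OR_MRNA	IL6	Interferon beta-2
mmp9	PROTEIN_OR_MRNA	MMP9	Matrix Metallopeptidase 9
mmp9	PROTEIN_OR_MRNA	MMP9	CLG4B
mmp9	PROTEIN_OR_MRNA	MMP9	92 kDa gelatinase
ngf	PROTEIN_OR_MRNA	NGF	Nerve Growth Factor
ngf	PROTEIN_OR_MRNA	NGF	NGFB
nos2	PROTEIN_OR_MRNA	NOS2	Nitric Oxide Synthase 2A
nos2	PROTEIN_OR_MRNA	NOS2	NOS2A
nos2	PROTEIN_OR_MRNA	NOS2	INOS
nos2	PROTEIN_OR_MRNA	NOS2	inducible nitric oxide synthase
pawr	PROTEIN_OR_MRNA	PAWR	PRKC apoptosis WT1 regulator
pawr	PROTEIN_OR_MRNA	PAWR	PAR4
pawr	PROTEIN_OR_MRNA	PAWR	prostate apoptosis response 4 protein
ptgs2	PROTEIN_OR_MRNA	PTGS2	Prostaglandin-Endoperoxide Synthase 2
ptgs2	PROTEIN_OR_MRNA	PTGS2	PGHS2
ptgs2	PROTEIN_OR_MRNA	PTGS2	COX2
ptgs2	PROTEIN_OR_MRNA	PTGS2	cyclooxygenase 2
tgfb1	PROTEIN_OR_MRNA	TGFB1	Transforming Growth Factor Beta 1
tgfb1	PROTEIN_OR_MRNA	TGFB1	TGF-beta 1
ttr	PROTEIN_OR_MRNA	TTR	Transthyretin
tnf	PROTEIN_OR_MRNA	TNF	Tumor Necrosis Factor
tnf	PROTEIN_OR_MRNA	TNF	TNFA
tnf	PROTEIN_OR_MRNA	TNF	TNF-alpha
plaur	PROTEIN_OR_MRNA	PLAUR	Urokinase Plasminogen Activator Receptor
plaur	PROTEIN_OR_MRNA	PLAUR	uPAR
plaur	PROTEIN_OR_MRNA	PLAUR	CD87
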