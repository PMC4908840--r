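gene	cluster	functional_category	alias	optional
ABCB1	bile_acid	transport		FALSE
ABCB11	bile_acid	transport	BSEP	FALSE
ABCB4	bile_acid	transport		FALSE
ABCC2	bile_acid	transport	MRP2	FALSE
ABCC3	bile_acid	transport		FALSE
ABCC4	bile_acid	transport		FALSE
ABCG1	bile_acid	transport		FALSE
ABCG5	bile_acid	transport		FALSE
ABCG8	bile_acid	transport		FALSE
ATP8B1	bile_acid	transport		FALSE
SLC10A1	bile_acid	transport	NTCP	FALSE
SLC10A2	bile_acid	transport	ASBT	FALSE
SLCO1A2	bile_acid	transport		FALSE
SLCO1B1	bile_acid	transport	OATP1B1	FALSE
SLCO1B3	bile_acid	transport	OATP1B3	FALSE
SLCO2B1	bile_acid	transport		FALSE
SLC51A	bile_acid	transport	OSTA	FALSE
SLC52A	bile_acid	transport	OSTB	FALSE
CYP27A1	bile_acid	synthesis_metabolism		FALSE
CYP39A1	bile_acid	synthesis_metabolism		FALSE
CYP3A4	bile_acid	synthesis_metabolism		FALSE
CYP7A1	bile_acid	synthesis_metabolism		FALSE
CYP7B1	bile_acid	synthesis_metabolism		FALSE
CYP8B1	bile_acid	synthesis_metabolism		FALSE
EPHX1	bile_acid	synthesis_metabolism	EPHX	FALSE
HSD3B7	bile_acid	synthesis_metabolism		FALSE
SCP2	bile_acid	synthesis_metabolism		FALSE
AKR1D1	bile_acid	synthesis_metabolism		FALSE
SULT2A1	bile_acid	synthesis_metabolism		FALSE
UGT2B11	bile_acid	synthesis_metabolism		FALSE
FGF19	bile_acid	signaling_regulation		FALSE
FGFR4	bile_acid	signaling_regulation		FALSE
NR1H4	bile_acid	signaling_regulation	FXR	FALSE
HNF1A	bile_acid	signaling_regulation	HNF1ALPHA	FALSE
NR2A1	bile_acid	signaling_regulation	HNF4A	FALSE
NR0B2	bile_acid	signaling_regulation	SHP	FALSE
NR1I2	bile_acid	signaling_regulation	PXR	FALSE
NR1I3	bile_acid	signaling_regulation	CAR	FALSE
NR5A2	bile_acid	signaling_regulation	LRH-1	FALSE
NR2B1	bile_acid	signaling_regulation	RXRA	FALSE
KL	bile_acid	signaling_regulation	KLOTHOB	FALSE
BAAT	bile_acid	conjugation		FALSE
SLC27A5	bile_acid	conjugation	BACS	FALSE
CYP1A1	drug_metabolism	phase1		FALSE
CYP1A2	drug_metabolism	phase1		FALSE
CYP2A6	drug_metabolism	phase1		FALSE
CYP2B6	drug_metabolism	phase1		FALSE
CYP2C8	drug_metabolism	phase1		FALSE
CYP2C9	drug_metabolism	phase1		FALSE
CYP2C19	drug_metabolism	phase1		FALSE
CYP2D6	drug_metabolism	phase1		FALSE
CYP2E1	drug_metabolism	phase1		FALSE
CYP3A4	drug_metabolism	phase1		FALSE
TPMT	drug_metabolism	phase1		FALSE
UGT1A1	drug_metabolism	phase2		FALSE
UGT1A4	drug_metabolism	phase2		FALSE
UGT2B7	drug_metabolism	phase2		FALSE
SULT1A1	drug_metabolism	phase2		FALSE
GSTM1	drug_metabolism	phase2		FALSE
GSTP1	drug_metabolism	phase2		FALSE
GSTT1	drug_metabolism	phase2		FALSE
SLC22A1	drug_metabolism	transport	OCT1	FALSE
SLC22A2	drug_metabolism	transport	OCT2	FALSE
SLC22A6	drug_metabolism	transport	OAT1	FALSE
SLC22A7	drug_metabolism	transport	OAT2	FALSE
SLC22A8	drug_metabolism	transport	OAT3	FALSE
SLC47A1	drug_metabolism	transport	MATE1	FALSE
SLCO1A2	drug_metabolism	transport		FALSE
SLCO1B1	drug_metabolism	transport	OATP1B1	FALSE
SLCO1B3	drug_metabolism	transport	OATP1B3	FALSE
SLCO2B1	drug_metabolism	transport		FALSE
ABCB1	drug_metabolism	transport	MDR1	FALSE
ABCC2	drug_metabolism	transport	MRP2	FALSE
ABCG2	drug_metabolism	transport	BCRP	FALSE
HNF1A	drug_metabolism	regulation	HNF1ALPHA	FALSE
NR2A1	drug_metabolism	regulation	HNF4A	FALSE
AHR	drug_metabolism	regulation		FALSE
NR1I2	drug_metabolism	regulation	PXR	FALSE
NR1I3	drug_metabolism	regulation	CAR	FALSE
NR3C1	drug_metabolism	regulation	GR	FALSE
PPARG	drug_metabolism	regulation		FALSE
NR2B1	drug_metabolism	regulation	RXRA	FALSE
NR3A1	drug_metabolism	regulation	ERALPHA	FALSE
NAT2	drug_metabolism	phase2		TRUE
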