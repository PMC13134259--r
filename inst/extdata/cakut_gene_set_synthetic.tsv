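hgnc_symbol	ensembl_id	evidence	inheritance
EYA1	ENSG00000104313	Definitive	AD
SIX1	ENSG00000126778	Definitive	AD
SIX2		Strong	AD
PAX2	ENSG00000075891	Definitive	AD
FOXC1		Strong	AD
FOXC2		Strong	AD
HNF1B	ENSG00000275410	Definitive	AD
GATA3	ENSG00000107485	Definitive	AD
HOXA11		Moderate	AD
ITGA8	ENSG00000077943	Strong	AR
MUC1	ENSG00000185499	Definitive	AD
NPNT		Moderate	AR
COL4A1	ENSG00000187498	Strong	AD
GFRA1		Moderate	AD
ETV3		Limited	AD
REN	ENSG00000143839	Definitive	AD
SALL1	ENSG00000103449	Definitive	AD
BNC2	ENSG00000173068	Strong	AD
CHRNA3		Moderate	AR
VWA2		Limited	AD
ROBO1		Moderate	AD
ROBO2	ENSG00000185008	Strong	AD
GREM1		Moderate	AD
UPK3A		Strong	AD
APP		Limited	AD
BCAM		Limited	AD
COL18A1		Moderate	AR
IGFBP7		Limited	AR
CALD1		Limited	AD
FOXP1		Moderate	AD
KCNQ1OT1		Limited	AD
VCAN		Limited	AD
RET	ENSG00000165731	Definitive	AD
GDNF		Strong	AD
BMP4		Strong	AD
BMP7		Moderate	AD
WNT4	ENSG00000162552	Definitive	AR
WNT9B		Moderate	AD
WT1	ENSG00000184937	Definitive	AD
FRAS1	ENSG00000138759	Definitive	AR
FREM1		Strong	AR
FREM2		Definitive	AR
GRIP1		Strong	AR
ANOS1		Strong	XL
CHD1L		Moderate	AD
DSTYK		Strong	AD
FGF20		Moderate	AR
FGFR2		Strong	AD
SOX17		Strong	AD
TBX18	ENSG00000112837	Strong	AD
TNXB		Strong	AD
TRAP1		Moderate	AR
NRIP1		Strong	AD
SLIT2		Moderate	AD
AGT		Definitive	AR
AGTR1		Definitive	AR
AGTR2		Strong	XL
ACE		Definitive	AR
HPSE2	ENSG00000172987	Definitive	AR
LRIG2		Definitive	AR
CHRM3		Strong	AR
MYOCD		Strong	AD
PBX1	ENSG00000185630	Definitive	AD
GREB1L	ENSG00000141449	Definitive	AD
ZMYM2		Strong	AD
CRKL		Strong	AD
TBX6		Strong	AD
GLI3		Strong	AD
GPC3		Strong	XL
KIF14		Moderate	AR
UMOD		Definitive	AD
HOXA13		Strong	AD
JAG1		Definitive	AD
NOTCH2		Definitive	AD
SIX5		Moderate	AD
SALL4		Strong	AD
UPK2		Moderate	AD
CHD7		Definitive	AD
KMT2D		Strong	AD
KAT6B		Moderate	AD
FGF10		Moderate	AD
FGFR1		Strong	AD
TFAP2A		Moderate	AD
DACT1		Limited	AD
CELSR1		Limited	AD
ESRRG		Limited	AD
LRP4		Moderate	AR
EP300		Moderate	AD
CREBBP		Moderate	AD
NFIA		Strong	AD
LIFR		Limited	AR
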