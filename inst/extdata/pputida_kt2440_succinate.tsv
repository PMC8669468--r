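# {"substrate":"succinate","normalization":"substrate uptake = 100","granularity":"curated central-carbon reconstruction; lumped steps: GAPDH+phosphatase chain expanded to PGK/GAPDH, aconitase split A/B; FADH2/ubiquinol lumped with NADH","note":"reconstruction from pathway topology, not a deposited model","species":"P. putida KT2440"}
id	equation	atom_map	reversible	kind	pathway	nadh_uqh2	nadph	atp
SUC_UPT	1 SUC_ext -> 1 SUC	SUC_ext:abcd -> SUC:abcd ; SUC_ext:abcd -> SUC:dcba	0	uptake	transport	0	0	0
SDH	1 SUC -> 1 FUM	SUC:abcd -> FUM:abcd ; SUC:abcd -> FUM:dcba	0	internal	TCA	1	0	0
FUMH	1 FUM -> 1 MAL	FUM:abcd -> MAL:abcd ; FUM:abcd -> MAL:dcba	1	internal	TCA	0	0	0
MDH	1 MAL -> 1 OAA	MAL:abcd -> OAA:abcd	1	internal	TCA	1	0	0
CS	1 OAA + 1 ACCOA -> 1 CIT	OAA:abcd + ACCOA:ef -> CIT:dcbfea	0	internal	TCA	0	0	0
ACONTA	1 CIT -> 1 ACO	CIT:abcdef -> ACO:abcdef	0	internal	TCA	0	0	0
ACONTB	1 ACO -> 1 ICIT	ACO:abcdef -> ICIT:abcdef	0	internal	TCA	0	0	0
ICDH	1 ICIT -> 1 AKG + 1 CO2	ICIT:abcdef -> AKG:abcde + CO2:f	0	internal	TCA	0	1	0
AKGDH	1 AKG -> 1 SUCCOA + 1 CO2	AKG:abcde -> SUCCOA:bcde + CO2:a	0	internal	TCA	1	0	0
SUCOAS	1 SUCCOA -> 1 SUC	SUCCOA:abcd -> SUC:abcd ; SUCCOA:abcd -> SUC:dcba	0	internal	TCA	0	0	1
ICL	1 ICIT -> 1 GLX + 1 SUC	ICIT:abcdef -> GLX:ab + SUC:cdef ; ICIT:abcdef -> GLX:ab + SUC:fedc	0	internal	glyoxylate	0	0	0
MALS	1 GLX + 1 ACCOA -> 1 MAL	GLX:ab + ACCOA:cd -> MAL:abdc	0	internal	glyoxylate	0	0	0
PCK	1 OAA -> 1 PEP + 1 CO2	OAA:abcd -> PEP:abc + CO2:d	0	internal	anaplerosis	0	0	-1
MAE	1 MAL -> 1 PYR + 1 CO2	MAL:abcd -> PYR:abc + CO2:d	0	internal	anaplerosis	1	0	0
PDH	1 PYR -> 1 ACCOA + 1 CO2	PYR:abc -> ACCOA:bc + CO2:a	0	internal	EMP	1	0	0
PYK	1 PEP -> 1 PYR	PEP:abc -> PYR:abc	0	internal	EMP	0	0	1
ENO	1 PEP -> 1 PG2	PEP:abc -> PG2:abc	0	internal	EMP	0	0	0
PGM	1 PG2 -> 1 PG3	PG2:abc -> PG3:abc	0	internal	EMP	0	0	0
PGK	1 PG3 -> 1 BPG	PG3:abc -> BPG:abc	0	internal	EMP	0	0	-1
GAPDH	1 BPG -> 1 GAP	BPG:abc -> GAP:abc	0	internal	EMP	-1	0	0
TPI	1 GAP -> 1 DHAP	GAP:abc -> DHAP:cba	0	internal	EMP	0	0	0
FBA	1 DHAP + 1 GAP -> 1 FBP	DHAP:abc + GAP:def -> FBP:abcdef	0	internal	EMP	0	0	0
FBP	1 FBP -> 1 F6P	FBP:abcdef -> F6P:abcdef	0	internal	EMP	0	0	0
PGI	1 F6P -> 1 G6P	F6P:abcdef -> G6P:abcdef	0	internal	EMP	0	0	0
RPI	1 RU5P -> 1 R5P	RU5P:abcde -> R5P:abcde	0	internal	PP	0	0	0
RPE	1 X5P -> 1 RU5P	X5P:abcde -> RU5P:abcde	0	internal	PP	0	0	0
TKT1	1 S7P + 1 GAP -> 1 X5P + 1 R5P	S7P:abfghij + GAP:cde -> X5P:abcde + R5P:fghij	0	internal	PP	0	0	0
TAL	1 E4P + 1 F6P -> 1 S7P + 1 GAP	E4P:defg + F6P:abchij -> S7P:abcdefg + GAP:hij	0	internal	PP	0	0	0
TKT2	1 F6P + 1 GAP -> 1 X5P + 1 E4P	F6P:abfghi + GAP:cde -> X5P:abcde + E4P:fghi	0	internal	PP	0	0	0
ASPTA	1 OAA -> 1 ASP	OAA:abcd -> ASP:abcd	0	internal	anabolism	0	0	0
GLUDH	1 AKG -> 1 GLU	AKG:abcde -> GLU:abcde	0	internal	anabolism	0	-1	0
THD	 -> 		0	internal	transhydrogenase	-1	1	0
CO2_EX	1 CO2 -> 1 CO2_ext	CO2:a -> CO2_ext:a	0	secretion	transport	0	0	0
MAL_IN	 -> 1 MAL	 -> MAL:abcd	0	unlabeled_influx	influx	0	0	0
PYR_IN	 -> 1 PYR	 -> PYR:abc	0	unlabeled_influx	influx	0	0	0
G6P_IN	 -> 1 G6P	 -> G6P:abcdef	0	unlabeled_influx	influx	0	0	0
DHAP_IN	 -> 1 DHAP	 -> DHAP:abc	0	unlabeled_influx	influx	0	0	0
ACCOA_IN	 -> 1 ACCOA	 -> ACCOA:ab	0	unlabeled_influx	influx	0	0	0
PPC	1 PEP + 1 CO2 -> 1 OAA	PEP:abc + CO2:d -> OAA:abcd	0	internal	anaplerosis	0	0	0
PYC	1 PYR + 1 CO2 -> 1 OAA	PYR:abc + CO2:d -> OAA:abcd	0	internal	anaplerosis	0	0	-1
ODX	1 OAA -> 1 PYR + 1 CO2	OAA:abcd -> PYR:abc + CO2:d	0	internal	anaplerosis	0	0	0
PPS	1 PYR -> 1 PEP	PYR:abc -> PEP:abc	0	internal	EMP	0	0	-2
ZWF	1 G6P -> 1 GL6P	G6P:abcdef -> GL6P:abcdef	0	internal	PP	0	1	0
PGL	1 GL6P -> 1 PG6	GL6P:abcdef -> PG6:abcdef	0	internal	PP	0	0	0
GND	1 PG6 -> 1 RU5P + 1 CO2	PG6:abcdef -> RU5P:bcdef + CO2:a	0	internal	PP	0	1	0
EDD	1 PG6 -> 1 KDPG	PG6:abcdef -> KDPG:abcdef	0	internal	ED	0	0	0
EDA	1 KDPG -> 1 PYR + 1 GAP	KDPG:abcdef -> PYR:abc + GAP:def	0	internal	ED	0	0	0
ACK	1 ACCOA -> 1 ACE	ACCOA:ab -> ACE:ab	0	internal	overflow	0	0	1
ACE_EX	1 ACE -> 1 ACE_ext	ACE:ab -> ACE_ext:ab	0	secretion	overflow	0	0	0
PYR_EX	1 PYR -> 1 PYR_ext	PYR:abc -> PYR_ext:abc	0	secretion	overflow	0	0	0
BM_G6P	1 G6P -> 		0	biomass_drain	biomass	0	0	0
BM_F6P	1 F6P -> 		0	biomass_drain	biomass	0	0	0
BM_R5P	1 R5P -> 		0	biomass_drain	biomass	0	0	0
BM_E4P	1 E4P -> 		0	biomass_drain	biomass	0	0	0
BM_GAP	1 GAP -> 		0	biomass_drain	biomass	0	0	0
BM_PG3	1 PG3 -> 		0	biomass_drain	biomass	0	0	0
BM_PEP	1 PEP -> 		0	biomass_drain	biomass	0	0	0
BM_PYR	1 PYR -> 		0	biomass_drain	biomass	0	0	0
BM_ACCOA	1 ACCOA -> 		0	biomass_drain	biomass	0	0	0
BM_OAA	1 OAA -> 		0	biomass_drain	biomass	0	0	0
BM_AKG	1 AKG -> 		0	biomass_drain	biomass	0	0	0
BM_ASP	1 ASP -> 		0	biomass_drain	biomass	0	0	0
BM_GLU	1 GLU -> 		0	biomass_drain	biomass	0	0	0
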