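id	equation	reversible	lower_bound	upper_bound	is_exchange	is_measured	subsystem
EX_glc	glc_e ->	TRUE	-1000	1000	TRUE	TRUE	transport
EX_lac	lac_e ->	TRUE	-1000	1000	TRUE	TRUE	transport
EX_nh4	nh4_e ->	TRUE	-1000	1000	TRUE	TRUE	transport
EX_asn	asn_e ->	TRUE	-1000	1000	TRUE	TRUE	transport
EX_asp	asp_e ->	TRUE	-1000	1000	TRUE	TRUE	transport
EX_glu	glu_e ->	TRUE	-1000	1000	TRUE	TRUE	transport
EX_ser	ser_e ->	TRUE	-1000	1000	TRUE	TRUE	transport
EX_ile	ile_e ->	TRUE	-1000	1000	TRUE	TRUE	transport
EX_leu	leu_e ->	TRUE	-1000	1000	TRUE	TRUE	transport
EX_o2	o2_e ->	TRUE	-1000	1000	TRUE	FALSE	transport
EX_co2	co2_e ->	TRUE	-1000	1000	TRUE	FALSE	transport
EX_biomass	biomass_e ->	FALSE	0	1000	TRUE	TRUE	biomass
EX_mab	mab_e ->	FALSE	0	1000	TRUE	TRUE	product
GLCt	glc_e -> glc	FALSE	0	1000	FALSE	FALSE	transport
LACt	lac -> lac_e	TRUE	-1000	1000	FALSE	FALSE	transport
NH4t	nh4 -> nh4_e	TRUE	-1000	1000	FALSE	FALSE	transport
ASNt	asn_e -> asn	FALSE	0	1000	FALSE	FALSE	transport
ASPt	asp_e -> asp	TRUE	-1000	1000	FALSE	FALSE	transport
GLUt	glu_e -> glu	TRUE	-1000	1000	FALSE	FALSE	transport
SERt	ser_e -> ser	FALSE	0	1000	FALSE	FALSE	transport
ILEt	ile_e -> ile	FALSE	0	1000	FALSE	FALSE	transport
LEUt	leu_e -> leu	FALSE	0	1000	FALSE	FALSE	transport
O2t	o2_e -> o2	FALSE	0	1000	FALSE	FALSE	transport
CO2t	co2 -> co2_e	FALSE	0	1000	FALSE	FALSE	transport
GLYC	glc -> 2 pyr + 2 atp + 2 nadh_c	FALSE	0	1000	FALSE	FALSE	glycolysis
PPP_OX	glc -> 6 co2	FALSE	0	1000	FALSE	FALSE	PPP
LDH	pyr + nadh_c -> lac	TRUE	-1000	1000	FALSE	FALSE	glycolysis
NADH_SHUTTLE	nadh_c -> fadh2	FALSE	0	1000	FALSE	FALSE	energy
PDH	pyr -> accoa + co2 + nadh_m	FALSE	0	1000	FALSE	FALSE	TCA
CS_IDH	accoa + oaa -> akg + co2 + nadh_m	FALSE	0	1000	FALSE	FALSE	TCA
AKGDH_MDH	akg -> oaa + co2 + 2 nadh_m + fadh2 + atp	FALSE	0	1000	FALSE	FALSE	TCA
PC	pyr + co2 + atp -> oaa	FALSE	0	1000	FALSE	FALSE	anaplerosis
ME	oaa -> pyr + co2	FALSE	0	1000	FALSE	FALSE	anaplerosis
OXPHOS_NADH	nadh_m + 0.5 o2 -> 3 atp	FALSE	0	1000	FALSE	FALSE	energy
OXPHOS_FADH	fadh2 + 0.5 o2 -> 2 atp	FALSE	0	1000	FALSE	FALSE	energy
ATPM	atp ->	FALSE	0	1000	FALSE	FALSE	energy
ASN_DEG	asn -> asp + nh4	FALSE	0	1000	FALSE	FALSE	amino_acid
ASP_TA	asp + akg -> glu + oaa	TRUE	-1000	1000	FALSE	FALSE	amino_acid
GDH	glu -> akg + nh4 + nadh_m	TRUE	-1000	1000	FALSE	FALSE	amino_acid
SER_DEG	ser -> pyr + nh4	FALSE	0	1000	FALSE	FALSE	amino_acid
ILE_DEG	ile -> accoa + oaa + nh4	FALSE	0	1000	FALSE	FALSE	amino_acid
LEU_DEG	leu -> 3 accoa + nh4	FALSE	0	1000	FALSE	FALSE	amino_acid
BIOMASS	0.2 glc + 0.1 asn + 0.05 asp + 0.05 glu + 0.05 ser + 0.02 ile + 0.02 leu + 0.1 accoa + 0.05 oaa + 2 atp -> biomass_e	FALSE	0	1000	FALSE	FALSE	biomass
MAB	0.3 asn + 0.2 asp + 0.25 glu + 0.25 ser + 0.15 ile + 0.2 leu + 4 atp -> mab_e	FALSE	0	1000	FALSE	FALSE	product
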