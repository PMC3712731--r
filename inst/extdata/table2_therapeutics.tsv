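therapeutic	reference_id	specificity	pathway	binding_mode
17-AAG	ChEBI:64153	HSP90	Signaling by EGFR in Cancer	non_covalent
17-DMAG	ChEBI:65324	HSP90	Signaling by EGFR in Cancer	non_covalent
Afatinib	ChEBI:61390	EGFR, ERBB2	Signaling by EGFR in Cancer	covalent
Canertinib	ChEBI:61399	Pan-ERBB	Signaling by EGFR in Cancer	covalent
Cetuximab	Recombinant antibody	EGFR	Signaling by EGFR in Cancer	not_applicable
Erlotinib	ChEBI:114785	EGFR	Signaling by EGFR in Cancer	non_covalent
Gefitinib	ChEBI:49668	EGFR	Signaling by EGFR in Cancer	non_covalent
Geldanamycin	ChEBI:5292	HSP90	Signaling by EGFR in Cancer	non_covalent
HKI-272	ChEBI:61390	EGFR, ERBB2	Signaling by EGFR in Cancer	covalent
Herbimycin A	ChEBI:5674	HSP90	Signaling by EGFR in Cancer	non_covalent
Lapatinib	ChEBI:49603	EGFR, ERBB2	Signaling by EGFR in Cancer	non_covalent
Pelitinib	ChEBI:38927	EGFR	Signaling by EGFR in Cancer	covalent
Vandetanib	ChEBI:49960	EGFR, VEGFR	Signaling by EGFR in Cancer	non_covalent
WZ4002	ChEBI:61400	EGFR	Signaling by EGFR in Cancer	covalent
IPI-504	Pending	HSP90	Signaling by EGFR in Cancer	non_covalent
AZ 2171	ChEBI:556867	FGFR, PDGFR, VEGFR. KIT	Signaling by FGFR in Disease	non_covalent
Brivanib	ChEBI:443041	FGFR, VEGFR	Signaling by FGFR in Disease	non_covalent
Brivanib alaninate	ChEBI:270995	FGFR, VEGFR	Signaling by FGFR in Disease	non_covalent
Dovitinib	ChEBI:594834	FGFR, FLT3, VEGFR, PDGFR, KIT, CSFR	Signaling by FGFR in Disease	non_covalent
E3810	Pending	FGFR, VEGFR	Signaling by FGFR in Disease	non_covalent
E7080	ChEBI:816009	FGFR VEGFR, PDGFR	Signaling by FGFR in Disease	non_covalent
Masitinib	ChEBI:63450	FGFR3, PDGFR, KIT	Signaling by FGFR in Disease	non_covalent
GP369	Recombinant antibody	FGFR2b	Signaling by FGFR in Disease	not_applicable
Midostaurin	ChEBI:63452	FGFR, FLT3, PDGFR, VEGFR, KIT, PKCA	Signaling by FGFR in Disease	non_covalent
PD173074	ChEBI:63448	Pan-FGFR	Signaling by FGFR in Disease	non_covalent
AZD4547	ChEBI:63453	Pan-FGFR	Signaling by FGFR in Disease	non_covalent
BGJ398	ChEBI:63451	Pan-FGFR	Signaling by FGFR in Disease	non_covalent
SU5402	ChEBI:63449	FGFR, VEGFR	Signaling by FGFR in Disease	non_covalent
GSK1059615	Pending	Pan-PI3K	PI3K/AKT Signaling in Cancer	non_covalent
BEZ235	Pending	PI3K Class I, mTOR	PI3K/AKT Signaling in Cancer	non_covalent
BGT226	Pending	PI3K Class I, mTOR	PI3K/AKT Signaling in Cancer	non_covalent
BKM120	Pending	PI3K Class I	PI3K/AKT Signaling in Cancer	non_covalent
XL765	Pending	PI3K Class I, mTOR	PI3K/AKT Signaling in Cancer	non_covalent
XL147	Pending	PI3K Class I	PI3K/AKT Signaling in Cancer	non_covalent
GDC0941	ChEBI:65326	PI3K Class I	PI3K/AKT Signaling in Cancer	non_covalent
PX-866	ChEBI:65345	PIK3CA, PIK3CD, PIK3CG	PI3K/AKT Signaling in Cancer	covalent
LY294002	ChEBI:65329	Pan-PI3K	PI3K/AKT Signaling in Cancer	non_covalent
wortmannin	ChEBI:52289	Pan-PI3K	PI3K/AKT Signaling in Cancer	covalent
Perifosine	ChEBI:428891	AKT	PI3K/AKT Signaling in Cancer	non_covalent
MK2206	ChEBI:716367	AKT	PI3K/AKT Signaling in Cancer	non_covalent
Triciribine	ChEBI:65310	AKT	PI3K/AKT Signaling in Cancer	non_covalent
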