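name	description	accession	category	nfkb_flag	gene_match_flag
AKR1	Akirin1	Q9H9L7	A	TRUE	FALSE
ACTR10	Actin related protein 10	Q9NZ32	A	FALSE	FALSE
RNF10	RING finger protein 10	Q8N5U6	A	TRUE	FALSE
SF3A1	Splicing factor 3a subunit 1	Q15459	A	FALSE	FALSE
THRAP5	Mediator of RNA polymerase II transcription subunit 16	Q9Y2X0	A	TRUE	FALSE
AKR2	Akirin2	Q53H80	B	TRUE	FALSE
ESRRG	Estrogen related receptor gamma	P62508	B	TRUE	FALSE
PITPNA	Phosphatidylinositol transfer protein alpha isoform	Q00169	B	FALSE	FALSE
ATF4	Cyclic AMP-dependent transcription factor ATF-4	P18848	D	FALSE	FALSE
C12orf10	Chromosome 12 open reading frame 10	Q86UA3	D	FALSE	FALSE
CCNE1	G1/S-specific cyclin-E1	P24864	D	FALSE	FALSE
CDC23	Cell division cycle protein 23 homolog	Q9UJX2	D	FALSE	FALSE
CLIC3	Chloride intracellular channel protein 3	O95833	D	FALSE	FALSE
CLTCL1	Clathrin heavy chain 2	P53675	D	FALSE	FALSE
CNOT3	CCR4-NOT transcription complex subunit 3	O75175	D	FALSE	FALSE
EXPH5	Exophilin 5	Q149M6	D	FALSE	FALSE
EZR	Ezrin	P15311	D	FALSE	FALSE
FNTA	Protein farnesyltransferase/geranylgeranyltransferase type-1 subunit alpha	P49354	D	FALSE	FALSE
HEG1	Protein HEG homolog 1	Q9ULI3	D	FALSE	FALSE
HNRPF	Heterogeneous nuclear ribonucleoprotein F	P52597	D	FALSE	FALSE
IFT57	Intraflagellar transport protein 57 homolog	Q9NWB7	D	FALSE	FALSE
INTS2	Integrator complex subunit 2	Q9H0H0	D	FALSE	FALSE
IRF6	Interferon regulatory factor 6	O14896	D	TRUE	FALSE
KLHL5	Kelch-like 5 isoform 2 variant	Q59HD9	D	FALSE	FALSE
LIMS1	LIM and senescent cell antigen-like-containing domain protein 1	P48059	D	FALSE	FALSE
LNX1	E3 ubiquitin-protein ligase LNX	Q8TBB1	D	FALSE	FALSE
PKM	Pyruvate kinase PKM	P14618	D	FALSE	FALSE
SCFD1	Sec1 family domain-containing protein 1	Q8WVM8	D	FALSE	FALSE
SERPINE2	Glia-derived nexin	P07093	D	FALSE	FALSE
SF3B1	Splicing factor 3B subunit 1	O75533	D	FALSE	FALSE
SPG21	Maspardin	Q9NZD8	D	FALSE	FALSE
SPTBN1 var 1	Spectrin beta chain, non-erythrocytic 1	Q01082	D	FALSE	FALSE
TOPBP1	DNA topoisomerase 2-binding protein 1	Q92547	D	FALSE	FALSE
URB2	Unhealthy ribosome biogenesis protein 2 homolog	Q14146	D	FALSE	FALSE
USP7	Ubiquitin carboxyl-terminal hydrolase 7	Q93009	D	FALSE	FALSE
VPS39	Vam6/Vps39-like protein	Q96JC1	D	FALSE	FALSE
WNT2	Protein Wnt-2	P09544	D	TRUE	FALSE
ZNF862	Zinc finger protein 862	O60290	D	FALSE	FALSE
GAREM1	GRB2-associated and regulator of MAPK protein1	Q9H706	D	FALSE	TRUE
Mitochondrion	Mitochondrion, complete genome	MF992925	D	FALSE	TRUE
RBPMS	RNA binding protein, mRNA processing factor (RBPMS), on chromosome 8	NG_029534.1	D	FALSE	TRUE
BRD7	Bromodomain containing 7 (BRD7), on chromosome 16	NG_023418.1	D	FALSE	TRUE
LSS	Lanosterol synthase (LSS), on chromosome 21	NG_011510.1	D	FALSE	TRUE
DRC3	DRC3 gene, complete cds	AF282168.1	D	FALSE	TRUE
AF-6	AF-6, complete cds	AB011399.1	D	FALSE	TRUE
DAPK1	Death-associated protein kinase 1 (DAPK1) gene, complete cds	DQ436495.1	D	FALSE	TRUE
EDH17B2	17-beta-hydroxysteroid dehydrogenase (EDH17B2) gene, complete cds	U34879.1	D	FALSE	TRUE
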