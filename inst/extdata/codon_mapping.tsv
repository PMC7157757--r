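codon	formula	base_size	provenance
AAA	DD	2	extended
AAC	DDMR	2	extended
AAG	DDR	2	extended
AAU	DDL	2	extended
ACA	DM	2	extended
ACC	DMMR	2	extended
ACG	DMR	2	extended
ACU	DML	2	extended
AGA	DF	2	extended
AGC	DFMR	2	extended
AGG	DFR	2	extended
AGU	DFL	2	extended
AUA	DS	2	extended
AUC	DSMR	2	extended
AUG	DSR	2	extended
AUU	DSL	2	extended
CAA	MF	2	paper
CAC	MFMR	2	extended
CAG	MFR	2	extended
CAU	MFL	2	extended
CCA	DL	2	extended
CCC	DLMR	2	extended
CCG	DLR	2	extended
CCU	DLL	2	extended
CGA	DT	2	extended
CGC	DTMR	2	extended
CGG	DTR	2	extended
CGU	DTL	2	extended
CUA	RD	2	extended
CUC	RDMR	2	extended
CUG	RDR	2	extended
CUU	RDL	2	extended
GAA	RR	2	extended
GAC	RRMR	2	extended
GAG	RRR	2	extended
GAU	RRL	2	extended
GCA	DR	2	extended
GCC	DRMR	2	paper
GCG	DRR	2	paper
GCU	DRL	2	extended
GGA	SL	2	paper
GGC	SLDR	2	paper
GGG	SLR	2	extended
GGU	SLL	2	extended
GUA	RM	2	extended
GUC	RMMR	2	extended
GUG	RMR	2	extended
GUU	RML	2	extended
UAA	D	1	extended
UAC	DMR	1	extended
UAG	DR	1	extended
UAU	DL	1	extended
UCA	S	1	paper
UCC	SMR	1	paper
UCG	SR	1	paper
UCU	SL	1	paper
UGA	TM	1	extended
UGC	T	1	paper
UGG	TR	1	extended
UGU	TL	1	extended
UUA	R	1	extended
UUC	RMR	1	extended
UUG	RR	1	extended
UUU	RL	1	extended
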