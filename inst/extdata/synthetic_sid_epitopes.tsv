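protein_id	start	end	label	source
SYN_AKR2	135	168	synthetic-epitope-1	Q38
SYN_AKR2	159	195	synthetic-epitope-2	Q41
SYN_AKR2	30	45	synthetic-epitope-3	other
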