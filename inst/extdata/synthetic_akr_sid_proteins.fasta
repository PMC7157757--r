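>SYN_AKR2 synthetic akirin2-like protein (not a UniProt sequence)
DFKSNHTHHQALNHRGWHKIGLSNSYMNACNFEVHWTARCDAGPKPRNGKSEINRYKICAHSSNWRINWSMSCWTLTIFDQSPPENIRSWVRALAQCFIYQFEHIMTTSFNPELFLGETPGQSDSDLFRIAIQDFYHNTDNGTKTSAIHPEMECGAFCPRDVAQFYRIMNFDEPNFNSMNPKADGEQARVCCGTRLKEHIIPLYQDFKVF
>SYN_AKR1 synthetic akirin1-like paralog (not a UniProt sequence)
IFGSNHTEHRALNHNGWHKIGLSNSYMNADNFEVHPTAWCMAGPMPANRSSEINWYKICAISSNWRINWSYSCWTSTIFDQSPPENIRSWPRALAQCAIYQFEHEMNTSWEPEKFLGETPGQSDSDLFMIAIQDFYHNTDRGTKLSFKHPEMPCGAFCPRDLASFYRIMNFDAPHFNSMNPLANGEQARCCDGTRSKERIIPLYQDFKVF
>SYN_SUB synthetic subolesin-like ortholog (not a UniProt sequence)
DSKSNHTHHQALNHRGWHKIILSIHYMNAHNFGVHLTALCKFGPKPRFGKSEINRYKICAHGSPWRCNLSMSCWTLTIFDQYPPENIPSWVTALAQCFIYQFEQVMTTSFNPELRLGETPGQSDSQLFRIAIQDFYNNTDNGTSTSAIHPEMECGAFAPRDVFTFNRIMFFYVPNFNQMNPLADGEQAMVCCGIRLCEFIGPLYQDNKEF
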