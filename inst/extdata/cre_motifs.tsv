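name	iupac
ABRE	ACGTG
DRE_core	RCCGAC
MBS	CAACTG
MYC	CANNTG
ARE	AAACCA
Wbox	TTGACC
as1	TGACG
Gbox	CACGTG
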