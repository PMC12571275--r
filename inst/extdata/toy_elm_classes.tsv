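ELMIdentifier	Regex	Description
LIG_TOY_1	AA	Toy dialanine ligand motif
LIG_TOY_2	^M	Initiator methionine toy motif
DOC_TOY_3	P.P	Proline-x-proline docking toy motif
LIG_TOY_4	K[RK]K$	C-terminal basic toy motif
LIG_TOY_5	G{2,3}	Glycine stretch toy motif
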