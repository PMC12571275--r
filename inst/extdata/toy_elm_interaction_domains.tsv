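ELM identifier	Interaction Domain Id	Interaction Domain Description	Interaction Domain Name
LIG_TOY_1	PF99901	Toy ligand-binding domain 1	ToyDom1
LIG_TOY_2	PF99902	Toy ligand-binding domain 2	ToyDom2
DOC_TOY_3	PF99903	Toy docking domain 3	ToyDom3
LIG_TOY_4	PF99904	Toy ligand-binding domain 4	ToyDom4
LIG_TOY_1	PF99905	Second domain for class 1	ToyDom5
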