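pfam_a	pfam_b
PF00001	PF00002
PF00003	PF00004
PF00005.12	PF00006
PF00007	PF00007
PF00008	PF00009
PF00010	PF00011
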