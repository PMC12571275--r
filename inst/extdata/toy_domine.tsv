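PFAM1	PFAM2	confidence
PF00002	PF00001	HC
PF00012	PF00013	MC
PF00014	PF00015	HC
PF00016	PF00017	LC
NOTPFAM	PF00018	HC
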