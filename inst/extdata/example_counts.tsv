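#marker_allele=M #disease_allele=A
.	AA	Aa	aa
MM	15	29	14
Mm	7	46	34
mm	0	6	49
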