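alias	symbol
MCP-1	CCL2
SDF-1	CXCL12
Ki-67	MKI67
TGF-beta1	TGFB1
TGF-beta2	TGFB2
TGF-beta3	TGFB3
IL-10	IL10
M-CSF	CSF1
GM-CSF	CSF2
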