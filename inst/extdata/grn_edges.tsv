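source	target	sign	evidence
ID1	ZCN8	+	confirmed
ZCN8	ZMM4	+	putative
DLF1	ZMM4	+	confirmed
VGT1	ZmRAP2.7	-	confirmed
ZmRAP2.7	ZMM4	-	putative
ZMM4	ZMM4	+	proposed_feedback
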