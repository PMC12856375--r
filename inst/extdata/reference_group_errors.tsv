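feature	CN_error	AD_error
ADAS13	0.131	0.175
EcogPtTotal	0.140	0.140
FAQ	0.141	0.164
MoCA	0.237	0.091
RAVLT_immediate	0.179	0.116
RAVLT_pct_forgetting	0.122	0.209
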