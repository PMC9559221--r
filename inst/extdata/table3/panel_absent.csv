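target
B*35:02
DQB1*03:01/DQA1*05:05
B*27:02
A*02:13
DRB1*11:02
B*57:03
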