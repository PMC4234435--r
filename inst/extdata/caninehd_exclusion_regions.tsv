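1	13000000	15700000
15	10200000	13500000
36	16000000	19200000
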