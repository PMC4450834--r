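key_a	key_b	n
hcc	*	10
termx	*	8
termx	hcc	5
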