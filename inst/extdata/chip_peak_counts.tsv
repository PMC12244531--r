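category	count
active	1119
repressed	376
null	1024
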