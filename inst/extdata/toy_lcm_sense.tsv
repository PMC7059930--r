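lemma	sense_id	class
mieć	mieć-1	SV
biec	biec-1	DAV
pomagać	pomagać-1	IAV
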