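lemma	polarity
radosny	positive
wesoły	positive
miły	positive
szczęśliwy	positive
piękny	positive
smutny	negative
zły	negative
straszny	negative
przerażony	negative
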