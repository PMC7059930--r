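lemma	class
mieć	SV
myśleć	SV
wiedzieć	SV
podziwiać	SV
chcieć	SV
kopać	DAV
biec	DAV
skakać	DAV
lecieć	DAV
płynąć	DAV
pomagać	IAV
oszukiwać	IAV
dokuczać	IAV
zachęcać	IAV
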