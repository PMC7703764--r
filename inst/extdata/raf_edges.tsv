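from	to
PKC	Raf
PKC	Mek
PKC	Jnk
PKC	P38
PKC	PKA
PKA	Raf
PKA	Mek
PKA	Erk
PKA	Akt
PKA	Jnk
PKA	P38
Raf	Mek
Mek	Erk
Erk	Akt
Plcg	PIP2
Plcg	PIP3
Plcg	PKC
PIP3	PIP2
PIP2	PKC
PIP3	Akt
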