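# demo PPI network: two dense regions sharing CoreX, plus a stray tail
ApcA	ApcB
ApcA	ApcC
ApcA	CoreX
ApcB	ApcC
ApcB	CoreX
ApcC	CoreX
CoreX	BrcA
CoreX	BrcB
CoreX	BrcC
BrcA	BrcB
BrcA	BrcC
BrcB	BrcC
CoreX	Stray1
Stray1	Stray2
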