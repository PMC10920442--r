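form	expansion
jusqu'	jusque
lorsqu'	lorsque
puisqu'	puisque
quoiqu'	quoique
qu'	que
l'	le
d'	de
j'	je
n'	ne
s'	se
c'	ce
m'	me
t'	te
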