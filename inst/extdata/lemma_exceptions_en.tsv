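word	lemma
men	man
women	woman
children	child
wives	wife
lives	life
knives	knife
selves	self
feet	foot
teeth	tooth
mice	mouse
geese	goose
ladies	lady
has	have
had	have
does	do
did	do
done	do
went	go
gone	go
came	come
saw	see
seen	see
knew	know
known	know
said	say
told	tell
gave	give
given	give
took	take
taken	take
made	make
thought	think
spoke	speak
spoken	speak
heard	hear
found	find
got	get
kept	keep
left	leave
felt	feel
brought	bring
swore	swear
sworn	swear
wept	weep
beloved	beloved
blessed	blessed
wicked	wicked
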