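form	expansion
e'en	even
e'er	ever
ne'er	never
o'er	over
'tis	it is
'twas	it was
'twere	it were
'twill	it will
'twould	it would
'gainst	against
'mongst	amongst
'twixt	betwixt
th'	the
i'	in
o'	of
wi'	with
ha'	have
an't	and it
on't	on it
in't	in it
to't	to it
do't	do it
is't	is it
't	it
won't	will not
can't	cannot
shan't	shall not
ain't	is not
let's	let us
it's	it is
that's	that is
there's	there is
here's	here is
what's	what is
who's	who is
where's	where is
how's	how is
he's	he is
she's	she is
i'd	i would
he'd	he would
she'd	she would
we'd	we would
you'd	you would
they'd	they would
who'd	who would
i'm	i am
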