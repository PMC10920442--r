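word	pos
family	noun
folly	noun
belly	noun
lily	noun
melancholy	noun
italy	noun
ally	noun
holy	adjective
lovely	adjective
lonely	adjective
friendly	adjective
heavenly	adjective
goodly	adjective
manly	adjective
womanly	adjective
courtly	adjective
deadly	adjective
ugly	adjective
jolly	adjective
silly	adjective
beloved	adjective
loving	adjective
sweet	adjective
fair	adjective
tender	adjective
dear	adjective
young	adjective
old	adjective
handsome	adjective
beautiful	adjective
modest	adjective
chaste	adjective
innocent	adjective
noble	adjective
good	adjective
great	adjective
true	adjective
false	adjective
kind	adjective
gentle	adjective
soft	adjective
pure	adjective
holy	adjective
sound	adjective
sad	adjective
happy	adjective
proud	adjective
rich	adjective
poor	adjective
strong	adjective
weak	adjective
bright	adjective
dark	adjective
wild	adjective
mad	adjective
fond	adjective
warm	adjective
cold	adjective
cruel	adjective
hot	adjective
high	adjective
low	adjective
long	adjective
short	adjective
new	adjective
fresh	adjective
bad	adjective
wicked	adjective
brave	adjective
bold	adjective
wise	adjective
foolish	adjective
have	verb
has	verb
had	verb
do	verb
does	verb
did	verb
done	verb
go	verb
went	verb
gone	verb
come	verb
came	verb
see	verb
saw	verb
seen	verb
know	verb
knew	verb
known	verb
say	verb
said	verb
tell	verb
told	verb
give	verb
gave	verb
given	verb
take	verb
took	verb
taken	verb
make	verb
made	verb
think	verb
thought	verb
speak	verb
spoke	verb
spoken	verb
hear	verb
heard	verb
find	verb
found	verb
let	verb
get	verb
got	verb
keep	verb
kept	verb
leave	verb
left	verb
feel	verb
felt	verb
bring	verb
brought	verb
swear	verb
swore	verb
sworn	verb
die	verb
live	verb
kiss	verb
wed	verb
marry	verb
woo	verb
sigh	verb
weep	verb
wept	verb
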