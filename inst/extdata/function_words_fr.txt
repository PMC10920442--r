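le
la
les
un
une
des
du
de
au
aux
ce
cet
cette
ces
je
tu
il
elle
on
nous
vous
ils
elles
me
te
se
moi
toi
soi
lui
leur
mon
ma
mes
ton
ta
tes
son
sa
ses
notre
nos
votre
vos
leurs
qui
que
quoi
dont
où
et
ou
mais
ni
car
donc
or
si
quand
comme
lorsque
puisque
quoique
parce
à
en
dans
par
pour
sur
sous
avec
sans
chez
vers
entre
contre
depuis
pendant
avant
après
jusque
ne
pas
point
plus
moins
très
bien
mal
tout
toute
tous
toutes
aucun
aucune
chaque
quel
quelle
quels
quelles
y
ici
là
ainsi
alors
encore
jamais
toujours
souvent
peut
être
est
sont
était
étaient
suis
es
sommes
êtes
fut
sera
seront
serait
avoir
ai
as
a
avons
avez
ont
avait
avaient
eut
aura
oui
non
hélas
ô
ah
eh
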