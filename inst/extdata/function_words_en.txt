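a
an
the
this
that
these
those
i
me
my
mine
myself
thou
thee
thy
thine
thyself
he
him
his
himself
she
her
hers
herself
it
its
itself
we
us
our
ours
ourselves
you
ye
your
yours
yourself
yourselves
they
them
their
theirs
themselves
who
whom
whose
which
what
whatever
whoever
and
or
but
nor
for
yet
so
if
then
than
as
because
while
when
whenever
where
wherever
why
how
although
though
unless
until
till
since
of
in
on
at
by
to
from
with
without
within
into
unto
upon
under
over
above
below
between
betwixt
among
amongst
against
through
throughout
during
before
after
about
toward
towards
up
down
out
off
near
not
no
nay
yes
yea
aye
also
too
very
quite
rather
such
some
any
all
both
each
every
either
neither
few
many
much
more
most
little
less
least
other
another
again
ever
never
always
often
sometimes
soon
now
here
there
hence
thence
whence
hither
thither
whither
anon
else
even
only
just
still
already
perhaps
may
might
must
shall
should
will
would
can
could
o
oh
ah
alas
lo
hark
prithee
pray
tut
fie
hey
ho
hail
adieu
farewell
am
is
are
was
were
be
been
being
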