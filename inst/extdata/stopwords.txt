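a
an
the
and
or
but
if
then
so
because
as
of
at
by
for
with
about
into
through
to
from
in
on
off
over
under
again
once
here
there
when
where
why
how
all
any
both
each
few
more
most
other
some
such
only
own
same
than
too
very
just
i
me
my
mine
myself
we
us
our
ours
you
your
yours
he
him
his
she
her
hers
it
its
they
them
their
theirs
this
that
these
those
am
is
are
was
were
be
been
being
have
has
had
having
do
does
did
doing
will
would
can
could
shall
should
may
might
must
not
no
nor
what
which
who
whom
um
uh
er
ah
hmm
mhm
uhm
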