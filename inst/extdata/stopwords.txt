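a
about
above
after
again
against
all
almost
also
although
always
am
among
amongst
an
and
another
any
anyhow
anyone
anything
anyway
anywhere
are
as
at
be
became
because
become
becomes
been
before
beforehand
being
below
beside
besides
between
beyond
both
but
by
can
cannot
could
did
do
does
done
due
during
each
either
else
elsewhere
enough
especially
etc
even
ever
every
everyone
everything
everywhere
except
few
for
former
formerly
found
from
further
had
has
have
having
he
hence
her
here
hereafter
hereby
herein
hereupon
hers
herself
him
himself
his
how
however
i
if
in
indeed
into
is
it
its
itself
just
kg
km
last
latter
latterly
least
less
made
mainly
make
many
may
me
meanwhile
mg
might
ml
mm
more
moreover
most
mostly
much
must
my
myself
namely
nearly
neither
never
nevertheless
next
no
nobody
none
noone
nor
not
nothing
now
nowhere
obtained
of
off
often
on
once
one
only
onto
or
other
others
otherwise
our
ours
ourselves
out
over
overall
own
per
perhaps
please
pmid
quite
rather
really
regarding
same
seem
seemed
seeming
seems
seen
several
she
should
show
showed
shown
shows
significantly
since
so
some
somehow
someone
something
sometime
sometimes
somewhere
still
such
than
that
the
their
theirs
them
themselves
then
thence
there
thereafter
thereby
therefore
therein
thereupon
these
they
this
those
though
through
throughout
thru
thus
to
together
too
toward
towards
under
until
up
upon
us
used
using
various
very
via
was
we
well
were
what
whatever
when
whence
whenever
where
whereafter
whereas
whereby
wherein
whereupon
wherever
whether
which
while
whither
who
whoever
whole
whom
whose
why
will
with
within
without
would
yet
you
your
yours
yourself
yourselves
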