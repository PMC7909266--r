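# Distractor vocabulary for the synthetic-cohort generator: task-irrelevant
# filler words screened (at load and in the test suite) against every lexicon
# variant and inflected form, the filler list, and the cue-phrase lists, so
# synthetic transcripts never produce accidental content-unit matches.
the
and
then
there
they
he
she
it
we
them
his
her
their
our
its
are
was
were
be
been
being
has
had
with
at
by
from
into
upon
onto
under
above
below
between
beyond
along
within
without
during
before
after
again
still
almost
rather
perhaps
maybe
probably
certainly
mostly
partly
slowly
quickly
gently
quietly
busy
tired
early
late
soon
often
seldom
never
always
away
anyway
indeed
thus
therefore
however
moreover
meanwhile
today
sometimes
somewhat
elsewhere
everywhere
anywhere
somewhere
about
against
despite
except
until
unless
since
when
where
why
how
which
who
whom
whose
these
those
both
either
neither
many
much
more
most
less
least
enough
thing
things
item
items
detail
details
moment
moments
piece
pieces
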