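# Common English words, ordered by approximate decreasing frequency.
# Lexicon surfaces whose lowercase form appears here are matched
# case-sensitively (common-language collision guard). One word per line.
the
of
and
a
to
in
is
was
he
for
it
with
as
his
on
be
at
by
i
this
had
not
are
but
from
or
have
an
they
which
one
you
were
her
all
she
there
would
their
we
him
been
has
when
who
will
more
no
if
out
so
said
what
up
its
about
into
than
them
can
only
other
new
some
could
time
these
two
may
then
do
first
any
my
now
such
like
our
over
man
me
even
most
made
after
also
did
many
before
must
through
back
years
where
much
your
way
well
down
should
because
each
just
those
people
how
too
little
state
good
very
make
world
still
own
see
men
work
long
get
here
between
both
life
being
under
never
day
same
another
know
while
last
might
us
great
old
year
off
come
since
against
go
came
right
used
take
three
states
himself
few
house
use
during
without
again
place
around
however
home
small
found
thought
went
say
part
once
general
high
upon
school
every
does
got
united
left
number
course
war
until
always
away
something
fact
though
water
less
public
put
think
almost
hand
enough
far
took
head
yet
government
system
better
set
told
nothing
night
end
why
called
didn
eyes
find
going
look
asked
later
knew
point
next
program
city
business
give
group
toward
young
days
let
room
within
change
present
case
order
given
several
national
possible
rather
second
face
per
among
form
important
often
things
looked
early
white
become
interest
large
big
need
four
felt
along
best
children
church
ever
least
power
thing
light
family
want
others
mind
country
area
done
open
god
service
certain
kind
different
problem
began
door
means
result
results
whole
itself
order
social
rather
seemed
side
clear
word
words
body
close
free
information
level
further
half
keep
name
nature
full
analysis
themselves
held
show
known
either
effect
taken
matter
today
member
members
percent
study
experience
question
real
sense
action
tax
believe
type
hours
local
above
already
table
necessary
particular
position
special
control
field
paper
similar
approach
value
natural
shown
observed
obtained
measured
sample
samples
section
condition
conditions
effects
increase
increased
decrease
report
reported
described
compared
relative
significant
consistent
previous
previously
experiment
experiments
finding
findings
method
figure
following
response
period
data
model
process
development
evidence
function
role
expression
sex
fold
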