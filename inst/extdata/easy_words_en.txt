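a
about
above
accord
across
act
add
afraid
after
afternoon
again
against
age
ago
ah
air
alas
all
almost
alone
along
already
also
although
always
am
among
an
and
angry
animal
another
answer
ant
any
anyone
anything
appear
apple
are
arm
around
ask
asleep
assess
assignment
at
ate
aunt
autumn
awake
away
baby
back
bad
bag
bake
ball
banana
bank
bark
base
basket
bath
bathroom
be
beach
bear
beat
beautiful
because
bed
bedroom
bee
been
before
began
begin
begun
behind
being
believe
bell
belong
below
belt
bench
bend
beside
best
better
between
bicycle
big
bill
bird
birthday
bit
bite
black
blanket
blow
blue
board
boat
body
bone
book
boot
born
borrow
both
bottle
bottom
bowl
box
boy
branch
brave
bread
break
breakfast
brick
bridge
bright
bring
broke
broken
brother
brought
brown
brush
build
built
burn
bus
busy
but
butter
button
buy
by
cake
call
came
camp
can
candy
cap
captain
car
card
care
careful
carried
carry
case
castle
cat
catch
cattle
caught
cause
cent
center
certain
chair
chalk
chance
change
chase
cheap
cheese
chicken
chief
child
children
choose
chose
chosen
church
circle
city
class
clean
cleaned
clear
clever
climb
clock
close
cloth
clothes
cloud
coat
coffee
cold
color
comb
come
consider
continue
convert
cook
cool
copy
corn
corner
cost
cotton
could
count
country
course
cover
cow
crack
cream
create
cross
crowd
cry
cup
cut
dance
dark
date
daughter
day
dead
dear
decide
decorate
decorated
deep
describe
desk
did
die
different
dig
dinner
dirty
dish
do
doctor
does
dog
dollar
done
door
double
down
drank
draw
drawn
dream
dress
drew
drink
drive
driven
drop
drove
drunk
dry
duck
during
dust
each
ear
early
earn
earth
east
easy
eat
eaten
edge
egg
eight
either
elephant
else
empty
end
enjoy
enough
enter
even
evening
ever
every
everyone
everything
examine
example
except
excuse
explain
eye
face
fact
fair
fall
fallen
family
far
farm
farmer
fast
fat
father
feed
feel
feet
fell
fellow
felt
fence
few
field
fight
fill
finally
find
fine
finger
finish
fire
first
fish
fit
five
fix
fixed
flag
flat
flew
floor
flower
flown
fly
follow
followed
food
foot
for
forest
forget
forgive
forgot
fork
form
forward
found
four
fox
free
fresh
friend
frog
from
fruit
full
fun
funny
game
garden
gate
gather
gave
gentle
get
gift
girl
give
given
glad
glass
go
goes
gold
gone
good
got
gotten
grain
grand
grass
gray
great
green
greet
grew
ground
group
grow
grown
guess
had
hair
half
hall
hand
handle
hang
happen
happy
hard
has
hat
hate
have
having
he
head
healthy
hear
heard
heart
heavy
held
helicopter
hello
help
helped
her
here
hers
herself
hey
hi
hide
high
hill
him
himself
his
hit
hmm
hold
hole
holiday
home
honey
hope
horse
hot
hour
house
however
hundred
hungry
hunt
hurry
hurt
i
ice
idea
if
important
in
include
inside
instead
into
iron
is
it
its
itself
job
join
joke
joy
juice
jump
just
keep
kept
key
kick
kill
kind
king
kitchen
kite
knee
knew
knife
knock
know
known
lady
lake
land
large
last
late
laugh
lazy
lead
leaf
learn
least
leave
left
leg
lend
less
lesson
let
letter
lift
light
like
line
lion
lip
list
listen
little
live
living
lock
log
long
look
lose
lost
loud
love
low
luck
lunch
made
mail
main
make
man
map
march
mark
market
mat
matter
may
maybe
me
meal
mean
meant
meat
meet
member
men
mend
met
middle
might
mile
milk
mind
mine
minute
miss
moment
money
monkey
month
moon
more
morning
most
mother
mountain
mouse
mouth
move
much
music
must
my
myself
nail
name
nap
near
neck
need
neighbor
nest
never
new
next
nice
night
nine
no
nobody
noise
none
noon
nor
north
nose
note
nothing
now
number
nurse
nut
ocean
of
offer
office
often
oh
oil
ok
okay
old
on
once
one
only
onto
oops
open
or
orange
order
other
our
ours
ourselves
outside
over
own
page
paid
pain
paint
painted
pair
pan
paper
parent
park
part
party
pass
past
pay
pen
pencil
penny
people
perhaps
person
pet
piano
pick
picnic
picture
pie
piece
pig
pin
place
plan
plant
plate
play
please
pocket
point
pond
pony
pool
poor
possible
post
pot
pour
present
pretty
professor
proud
pull
purr
push
put
queen
quick
quiet
quite
rabbit
race
radio
rain
rainy
raise
ran
rather
reach
read
ready
real
really
reason
red
remain
remember
rest
ribbon
rice
rich
ride
right
ring
rise
risen
river
road
rock
roll
roof
room
rope
rose
round
row
rub
rug
rule
run
sad
safe
said
salt
same
sand
sang
sat
save
saw
say
school
sea
season
seat
second
secret
see
seed
seem
seen
sees
sell
send
sent
sentence
serve
set
seven
several
shake
shall
shape
share
sharp
she
sheep
shelf
shine
ship
shirt
shoe
shop
shore
short
should
shout
show
shut
sick
side
sign
silver
simple
since
sing
sister
sit
six
size
skin
sky
sled
sleep
sleeps
slept
slow
small
smell
smile
smoke
snake
snow
soap
sock
soft
sold
some
someone
something
sometimes
son
song
soon
sorry
sound
soup
south
space
speak
spell
spend
spent
spoke
spoken
spoon
spot
spring
square
stair
stamp
stand
star
start
state
station
stay
step
stick
still
stone
stood
stop
store
storm
story
straight
strange
street
strong
student
such
sudden
sugar
suit
summer
sun
sung
sunny
supper
sure
surprise
swam
sweet
swim
swum
table
tail
take
taken
tale
talk
tall
taught
tea
teach
teacher
team
tear
teeth
tell
ten
tent
test
thank
that
the
their
theirs
them
themselves
then
there
these
they
thick
thin
thing
think
third
this
those
though
thought
thousand
three
threw
through
throw
thrown
ticket
tie
tiger
till
time
tiny
tip
tired
to
today
toe
together
told
tomato
tomorrow
tonight
too
took
tooth
top
touch
toward
towards
town
toy
trade
train
tree
trick
tried
trip
truck
true
trust
try
turn
twelve
twenty
twice
two
uh
um
umbrella
uncle
under
understand
understood
unless
until
upon
us
use
usually
valley
very
village
visit
visited
voice
wagon
wait
wake
walk
wall
want
warm
was
wash
washed
waste
watch
watched
water
watermelon
we
weak
wear
weather
week
weekend
well
went
were
west
wet
what
wheel
when
whereas
whether
which
while
white
who
whole
whom
whose
wide
wild
will
win
wind
window
wing
winter
wise
wish
with
within
without
woke
wolf
woman
women
won
wonder
wonderful
wood
wool
word
wore
work
world
worm
worn
worry
would
wow
write
written
wrote
yard
yeah
year
yellow
yes
yesterday
yet
you
young
your
yours
yourself
zero
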