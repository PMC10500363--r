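# Synthetic easy-word list (approximate reconstruction).
# One lowercase word per line; lines starting with "#" are comments.
# This is NOT the copyrighted New Dale-Chall list: it is a hand-written
# approximation of that kind of list -- common English words a young
# reader is expected to know. Lookup is case-insensitive and strips
# regular inflections (-s, -es, -ed, -ing) before matching.
a
able
about
above
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
agree
air
all
almost
alone
along
already
also
always
am
among
an
and
angry
animal
another
answer
any
anyone
anything
apple
are
arm
around
arrive
art
as
ask
asleep
at
ate
aunt
away
baby
back
bad
bag
bake
ball
banana
band
bank
bar
barn
basket
bath
be
bean
bear
beat
beautiful
became
because
become
bed
bee
been
before
began
begin
behind
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
big
bill
bird
birthday
bit
bite
black
blanket
blood
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
bought
bowl
box
boy
branch
brave
bread
break
breakfast
breath
breathe
brick
bridge
bright
bring
broke
brother
brought
brown
brush
build
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
car
card
care
careful
carry
cat
catch
caught
cause
cent
chair
chance
change
chase
cheap
check
cheek
cheese
chest
chicken
child
children
chin
choose
church
circle
city
class
clean
clear
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
come
cook
cool
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
cross
crowd
cry
cup
cut
dad
dance
danger
dark
day
dead
dear
decide
deep
deer
desk
did
die
different
dig
dinner
dirt
dirty
dish
do
doctor
does
dog
dollar
done
door
down
draw
dream
dress
drink
drive
drop
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
except
excuse
eye
face
fact
fair
fall
family
far
farm
farmer
fast
fat
father
fear
feed
feel
feet
fell
felt
fence
few
field
fight
fill
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
flag
flat
floor
flower
fly
follow
food
foot
for
forest
forget
forgot
fork
form
found
four
fox
free
fresh
friend
frog
from
front
fruit
full
fun
funny
game
garden
gate
gave
get
gift
girl
give
glad
glass
go
goat
goes
gold
gone
good
got
grade
grand
grandfather
grandmother
grass
gray
great
green
grew
ground
group
grow
guess
had
hair
half
hall
hand
hang
happen
happy
hard
has
hat
have
he
head
hear
heard
heart
heat
heavy
held
hello
help
hen
her
here
herself
hid
hide
high
hill
him
himself
his
hit
hold
hole
home
hope
horn
horse
hot
hour
house
how
hundred
hungry
hunt
hurry
hurt
i
ice
if
important
in
inch
inside
into
iron
is
it
its
itself
jacket
job
join
joke
jump
just
keep
kept
key
kick
kid
kill
kind
king
kiss
kitchen
kitten
knee
knew
knife
knock
know
ladder
lady
lake
lamp
land
large
last
late
laugh
lay
lazy
lead
leaf
learn
least
leave
left
leg
lemon
less
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
load
lock
log
long
look
lose
lost
lot
loud
love
low
lunch
mad
made
mail
make
man
many
map
march
mark
market
match
matter
may
maybe
me
meal
mean
meat
meet
men
met
middle
might
mile
milk
mind
mine
minute
miss
mistake
mix
mom
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
mud
music
must
my
myself
nail
name
near
neck
need
needle
neighbor
neither
nest
never
new
news
next
nice
night
nine
no
nobody
noise
none
noon
north
nose
not
note
nothing
now
number
nurse
nut
ocean
of
off
offer
office
often
oh
oil
old
on
once
one
only
open
or
orange
order
other
our
out
outside
over
own
page
paid
pail
pain
paint
pair
pan
paper
parent
park
part
party
pass
past
paste
pay
pea
peach
pen
pencil
penny
people
perhaps
person
pet
pick
picnic
picture
pie
piece
pig
pile
pin
pink
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
poor
pop
post
pot
potato
pour
present
pretty
pull
puppy
push
put
queen
question
quick
quiet
quit
quite
rabbit
race
radio
rain
raise
ran
ranch
rather
reach
read
ready
real
reason
red
remember
rest
return
ribbon
rice
rich
ride
right
ring
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
sail
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
seat
second
see
seed
seem
seen
sell
send
sent
set
seven
several
sew
shade
shake
shall
shape
share
sharp
she
sheep
shelf
shell
shine
ship
shirt
shoe
shop
short
shot
should
shoulder
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
sleep
slid
slide
slow
small
smell
smile
smoke
snake
snow
so
soap
sock
soft
sold
some
someone
something
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
spoke
spoon
spot
spring
square
squirrel
stair
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
stove
straight
strange
street
strong
such
sudden
sugar
suit
summer
sun
supper
sure
surprise
sweet
swim
table
tail
take
talk
tall
taste
teach
teacher
team
tear
teeth
tell
ten
tent
than
thank
that
the
their
them
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
tie
tiger
tight
time
tiny
tire
to
today
toe
together
told
tomorrow
tongue
tonight
too
took
tooth
top
touch
toward
town
toy
train
tree
trick
trip
truck
true
try
turn
twelve
twenty
two
ugly
umbrella
uncle
under
understand
until
up
upon
us
use
valley
very
village
visit
voice
wagon
wait
wake
walk
wall
want
war
warm
was
wash
watch
water
wave
way
we
wear
weather
week
well
went
were
west
wet
what
wheat
wheel
when
where
which
while
white
who
whole
whose
why
wide
wife
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
without
woke
woman
women
wonder
wood
word
wore
work
world
worm
worry
worse
would
write
wrong
yard
year
yellow
yes
yesterday
yet
you
young
your
yourself
zoo
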