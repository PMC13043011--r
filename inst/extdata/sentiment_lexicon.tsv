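word	valence
good	0.6
great	0.8
excellent	1.0
amazing	0.9
wonderful	0.9
fantastic	0.9
awesome	0.8
happy	0.8
happier	0.8
joy	0.9
joyful	0.9
glad	0.6
pleased	0.6
cheerful	0.7
content	0.4
calm	0.4
relaxed	0.5
peaceful	0.5
hopeful	0.6
optimistic	0.7
confident	0.6
proud	0.7
excited	0.7
energized	0.6
energetic	0.6
motivated	0.6
refreshed	0.5
rested	0.5
strong	0.4
fine	0.2
okay	0.1
better	0.4
best	0.8
love	0.9
loved	0.8
like	0.3
enjoy	0.6
enjoyed	0.6
fun	0.6
thankful	0.7
grateful	0.8
satisfied	0.6
accomplished	0.7
productive	0.5
positive	0.5
well	0.3
nice	0.4
supported	0.5
connected	0.4
bad	-0.6
terrible	-0.9
awful	-0.9
horrible	-0.9
worst	-0.9
sad	-0.8
sadness	-0.8
unhappy	-0.7
depressed	-0.9
depressing	-0.8
miserable	-0.9
down	-0.4
low	-0.4
blue	-0.3
gloomy	-0.6
hopeless	-0.9
worthless	-0.9
guilty	-0.6
ashamed	-0.7
lonely	-0.7
alone	-0.4
isolated	-0.6
anxious	-0.7
anxiety	-0.7
worried	-0.6
worry	-0.6
nervous	-0.5
afraid	-0.7
scared	-0.7
fear	-0.7
stressed	-0.7
stress	-0.6
overwhelmed	-0.7
frustrated	-0.6
frustrating	-0.6
angry	-0.7
anger	-0.7
annoyed	-0.5
irritable	-0.5
irritated	-0.5
upset	-0.6
hurt	-0.6
pain	-0.6
painful	-0.7
tired	-0.5
exhausted	-0.8
exhausting	-0.7
fatigued	-0.7
drained	-0.7
weary	-0.6
sleepy	-0.3
drowsy	-0.4
sluggish	-0.5
weak	-0.4
sick	-0.6
unwell	-0.5
struggle	-0.6
struggling	-0.6
difficult	-0.4
hard	-0.3
rough	-0.4
tough	-0.3
worse	-0.5
hate	-0.9
hated	-0.8
dislike	-0.5
bored	-0.4
boring	-0.4
empty	-0.5
numb	-0.5
restless	-0.4
tense	-0.5
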