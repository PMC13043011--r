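sad
sadness
unhappy
depressed
depressing
miserable
gloomy
hopeless
worthless
guilty
ashamed
lonely
isolated
anxious
anxiety
worried
worry
nervous
afraid
scared
fear
stressed
stress
overwhelmed
frustrated
frustrating
angry
anger
annoyed
irritable
irritated
upset
hurt
exhausted
fatigued
drained
weary
terrible
awful
horrible
hate
hated
empty
numb
restless
tense
tired
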