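happy
happier
joy
joyful
glad
pleased
cheerful
hopeful
optimistic
confident
proud
excited
energized
energetic
motivated
refreshed
rested
love
loved
enjoy
enjoyed
thankful
grateful
satisfied
accomplished
calm
relaxed
peaceful
content
wonderful
great
amazing
fantastic
awesome
excellent
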