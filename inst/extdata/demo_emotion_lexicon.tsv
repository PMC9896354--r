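word	category	flag
furious	anger	1
outraged	anger	1
irritated	anger	1
resentful	anger	1
angered	anger	1
expectation	anticipation	1
awaiting	anticipation	1
eagerness	anticipation	1
foresee	anticipation	1
anticipate	anticipation	1
revulsion	disgust	1
repulsed	disgust	1
nauseating	disgust	1
loathing	disgust	1
disgusted	disgust	1
afraid	fear	1
scared	fear	1
terrified	fear	1
dread	fear	1
panic	fear	1
worried	fear	1
frightened	fear	1
anxious	fear	1
delighted	joy	1
cheerful	joy	1
joyful	joy	1
elated	joy	1
gladness	joy	1
sorrow	sadness	1
grieving	sadness	1
mournful	sadness	1
tearful	sadness	1
heartbroken	sadness	1
astonished	surprise	1
startled	surprise	1
amazed	surprise	1
stunned	surprise	1
unexpected	surprise	1
reliable	trust	1
faithful	trust	1
trustworthy	trust	1
dependable	trust	1
reassured	trust	1
wonderful	positive	1
excellent	positive	1
marvelous	positive	1
superb	positive	1
pleasant	positive	1
admirable	positive	1
awful	negative	1
horrible	negative	1
nasty	negative	1
unpleasant	negative	1
miserable	negative	1
painful	negative	1
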