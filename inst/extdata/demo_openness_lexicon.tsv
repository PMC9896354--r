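ngram	score	source
spoke openly	3	corpus
shared everything immediately	3	corpus
told relatives directly	3	corpus
discussed risks honestly	3	corpus
kept secret	-3	corpus
avoided telling anyone	-3	corpus
refused discussing results	-3	corpus
hid diagnosis	-3	corpus
talk	1	thesaurus
conversation	1	thesaurus
communicate	2	thesaurus
informed	2	thesaurus
disclosure	2	thesaurus
dialogue	2	thesaurus
openness	3	thesaurus
silence	-2	thesaurus
secrecy	-3	thesaurus
concealment	-3	thesaurus
unspoken	-2	thesaurus
avoidance	-2	thesaurus
open conversation	3	thesaurus
good communication	2	thesaurus
honest exchange	3	thesaurus
family meeting	1	thesaurus
regular contact	2	thesaurus
close contact	2	thesaurus
communication barrier	-2	thesaurus
broken contact	-3	thesaurus
strained relationship	-2	thesaurus
awkward silence	-2	thesaurus
poor communication	-2	thesaurus
difficult topic	-1	thesaurus
whole family knows	3	thesaurus
everybody felt informed	2	thesaurus
freely exchanged news	3	thesaurus
always felt heard	2	thesaurus
nobody ever mentioned	-3	thesaurus
never talked anymore	-3	thesaurus
completely stopped talking	-3	thesaurus
rarely mentioned anything	-2	thesaurus
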