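word	score
wonderful	4
excellent	3
marvelous	4
superb	3
pleasant	2
admirable	2
delighted	3
cheerful	2
reassured	2
awful	-3
horrible	-3
nasty	-3
unpleasant	-2
miserable	-2
painful	-2
scared	-2
terrified	-4
sorrow	-2
worried	-2
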