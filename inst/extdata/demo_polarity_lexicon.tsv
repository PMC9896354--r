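word	polarity
wonderful	positive
excellent	positive
marvelous	positive
superb	positive
pleasant	positive
admirable	positive
delighted	positive
cheerful	positive
reassured	positive
awful	negative
horrible	negative
nasty	negative
unpleasant	negative
miserable	negative
painful	negative
scared	negative
terrified	negative
sorrow	negative
worried	negative
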