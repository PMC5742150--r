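# AI Escargot (Arto Inkala), 23 clues; row-major, 0 = blank.
100007090
030020008
009600500
005300900
010080002
600004000
300000010
040000007
007000300
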