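# SYNTHETIC hard Sudoku (26 clues, unique solution), generated as a
# representative hard instance; row-major, 0 = blank.
403057000
015300000
000000900
090000600
002800000
004001009
000206800
006000005
020538016
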