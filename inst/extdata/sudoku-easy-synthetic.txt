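# SYNTHETIC easy Sudoku (36 clues, unique solution), generated as a
# representative easy instance; row-major, 0 = blank.
003950261
905302000
060000050
100400002
650093000
070001089
031046800
040719020
700500010
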