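c Canadian provinces and territories land-border adjacency
c (PE is an island with no land border)
c vertex 1 = BC
c vertex 2 = AB
c vertex 3 = SK
c vertex 4 = MB
c vertex 5 = ON
c vertex 6 = QC
c vertex 7 = NB
c vertex 8 = NS
c vertex 9 = PE
c vertex 10 = NL
c vertex 11 = YT
c vertex 12 = NT
c vertex 13 = NU
p edge 13 15
e 1 2
e 1 11
e 1 12
e 2 3
e 2 12
e 3 4
e 3 12
e 4 5
e 4 13
e 5 6
e 6 7
e 6 10
e 7 8
e 11 12
e 12 13
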