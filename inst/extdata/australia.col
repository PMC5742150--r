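c Australian states and territories land-border adjacency
c vertex 1 = WA
c vertex 2 = NT
c vertex 3 = SA
c vertex 4 = QLD
c vertex 5 = NSW
c vertex 6 = VIC
c vertex 7 = TAS
p edge 7 9
e 1 2
e 1 3
e 2 3
e 2 4
e 3 4
e 3 5
e 3 6
e 4 5
e 5 6
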