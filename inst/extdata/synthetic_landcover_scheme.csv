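code,phylogeny,herbaceous,sparse,closed_flooded,water,ratio_stratum
10,none,crop,0,0,0,none
20,none,crop,0,0,0,none
30,none,crop,0,0,0,none
50,angiosperm,grass,0,1,0,none
60,angiosperm,grass,0,0,0,none
70,gymnosperm,grass,0,0,0,none
80,gymnosperm,grass,0,0,0,none
90,mixed,grass,0,0,0,none
100,mixed,grass,0,0,0,none
110,mixed,grass,0,0,0,none
120,mixed,grass,0,0,0,shrub
122,mixed,grass,0,0,0,savannah
130,none,grass,0,0,0,none
140,none,grass,0,0,0,none
150,none,grass,1,0,0,none
160,angiosperm,grass,0,1,0,none
170,angiosperm,grass,0,1,0,none
180,mixed,grass,0,0,0,none
190,none,grass,0,0,0,none
200,none,grass,0,0,0,none
210,none,grass,0,0,1,none
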