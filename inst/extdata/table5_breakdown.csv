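combo,met_B.eyes,met_D.eyes,met_G.people,n_asd,pct_asd,n_td,pct_td
none,0,0,0,1,4.8,18,51.4
B.eyes only,1,0,0,2,9.5,5,14.3
D.eyes only,0,1,0,0,0.0,2,5.7
G.people only,0,0,1,1,4.8,3,8.6
B.eyes + D.eyes,1,1,0,5,23.8,3,8.6
B.eyes + G.people,1,0,1,2,9.5,0,0.0
D.eyes + G.people,0,1,1,1,4.8,1,2.9
all three,1,1,1,9,42.9,3,8.6
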