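t,psi
0.01,0.0021
0.03,0.0039
0.1,0.0076
0.3,0.014
1,0.028
3,0.061
10,0.16
30,0.44
100,1.4
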