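ga_week,upper_normal_ri
20,0.8
21,0.7915
22,0.783
23,0.7745
24,0.766
25,0.7575
26,0.749
27,0.7405
28,0.732
29,0.7235
30,0.715
31,0.7065
32,0.698
33,0.6895
34,0.681
35,0.6725
36,0.664
37,0.6555
38,0.647
39,0.6385
40,0.63
41,0.6215
42,0.613
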