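"time_h","release_pct"
1,1.192
2,1.870448
3,2.434474
4,2.935048
5,3.393179
6,3.820099
7,4.222698
8,4.605584
9,4.972032
10,5.324468
11,5.66476
12,5.994377
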