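timepoint,median_fi
0,100
5,149
10,120
40,105
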