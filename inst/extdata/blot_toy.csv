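blot,lane,target,actin
b1,1,100,100
b1,2,50,100
b1,3,80,160
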