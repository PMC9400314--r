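sample_id,condition,stain,median_fi
s1,activated,stained,150
s1,activated,unstained,10
s2,resting,stained,100
s2,resting,unstained,20
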