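sample_id,condition,timepoint,median_fi
s1,activated,30,150
s2,resting,30,100
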