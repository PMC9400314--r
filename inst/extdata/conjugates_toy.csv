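sample_id,singles_t,singles_b,conjugates,control_singles_t,control_singles_b,control_conjugates
exp1,4000,5000,500,4410,5000,90
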