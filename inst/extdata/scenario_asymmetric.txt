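# asymmetric feet: stepping (right) leg placed 10 cm backwards
name asymmetric_feet
seat_height 0.44
max_time 12
foot_offset_r -0.10
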