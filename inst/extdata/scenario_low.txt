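# low seat condition: 35 cm seat height
name low_seat
seat_height 0.35
max_time 12
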