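# normal seat condition: 44 cm seat height, symmetric feet
name normal_seat
seat_height 0.44
max_time 12
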