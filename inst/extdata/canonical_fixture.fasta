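>PROT1 synthetic canonical stand-in
MLLPQACDEFGHIKTTRSVVNNPLQAAKEDFGHTRRW
>PROT2 synthetic canonical stand-in
MAVVTTRKLPQNNSDEGHWFYCIKLMR
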