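name	sequence	orientation	annealing_c	pair	expected_fragment_bp
Dfd1fw	CAAGCGGCAGCGGACNCSNTAYAC	forward	58	Dfd	160
Dfd1rev	TCTTCCTCCGCACGTTCTTNGTRTTNGG	reverse	57	Dfd	160
Scr1fw	GCAGCGGACCTCCTACACCMGNTAYCARAC	forward	62	Scr	128
Scr1rev	TCATGGTGGCCATCTTGTGYTCYTTYTTCC	reverse	57	Scr	128
Ubx3fw	GCCGGCAGACCTACACCMGNTAYCARAC	forward	61	Ubx	145
Ubx3rev	CTCCTGCTCGTTCAGCTCYTTDATNGC	reverse	57	Ubx	145
abdAfw	CGGCGGCGGGGNMGNCARAC	forward	59	abdA	164
abdArev	GGGCCTGCTCGTTGATCTCYTTNACNGC	reverse	60	abdA	164
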