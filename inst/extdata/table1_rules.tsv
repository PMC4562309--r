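antecedent	consequent	tt	tf	ft	ff	confidence	p_printed
urah&urad&!uox&!hpxO&!hpyO	COG3748	154	12	5	1519	0.928	1e-196
urad&!uox&!hpxO&!hpyO	COG3748	155	26	4	1505	0.856	1e-185
urad&!uox&!hpxO	COG3748	155	44	4	1487	0.779	2e-172
urad&!uox	COG3748	157	95	2	1436	0.623	6e-151
urad	COG3748	158	272	1	1259	0.367	1e-103
!uox	COG3748	158	1339	1	192	0.106	1e-8
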