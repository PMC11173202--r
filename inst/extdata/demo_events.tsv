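piece_id	user_id	parent_id	timestamp
p1	alice		0
p1	bob	alice	3
p1	carol	alice	5
p1	dave	bob	9
p2	bob		20
p2	carol	bob	22
p2	erin	carol	27
p3	alice		40
p3	bob	alice	41
p3	dave	bob	44
p4	erin		60
p4	carol	erin	63
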