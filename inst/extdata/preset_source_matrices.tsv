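source	from	A	C	G	T
pos	A	0.2	0.4	0.2	0.2
pos	C	0.2	0.2	0.4	0.2
pos	G	0.2	0.2	0.2	0.4
pos	T	0.4	0.2	0.2	0.2
alt	A	0.2	0.2	0.4	0.2
alt	C	0.2	0.2	0.2	0.4
alt	G	0.4	0.2	0.2	0.2
alt	T	0.2	0.4	0.2	0.2
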