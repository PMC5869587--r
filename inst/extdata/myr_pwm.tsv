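pos	aa	weight
2	G	3
2	A	-5
2	R	-5
2	N	-5
2	D	-5
2	C	-5
2	Q	-5
2	E	-5
2	H	-5
2	I	-5
2	L	-5
2	K	-5
2	M	-5
2	F	-5
2	P	-5
2	S	-5
2	T	-5
2	W	-5
2	Y	-5
2	V	-5
3	N	1
3	S	1
3	A	0.5
3	Q	0.5
3	C	0.5
3	T	0.5
3	G	0.3
3	D	-1
3	E	-1
3	R	-0.5
3	H	-0.5
3	P	-0.5
3	F	-0.5
3	Y	-0.5
3	W	-0.5
4	S	0.5
4	T	0.5
4	A	0.3
4	C	0.3
4	P	-1
5	S	0.5
5	T	0.5
5	A	0.3
5	K	0.3
5	C	0.3
6	S	1
6	T	1
6	A	0.5
6	G	0.5
6	C	0.5
6	N	0.5
6	D	-0.5
6	E	-0.5
7	S	0.5
7	T	0.5
7	A	0.3
7	C	0.3
7	K	0.3
7	P	-2
8	K	0.3
8	S	0.2
8	A	0.2
8	E	-0.3
8	D	-0.3
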