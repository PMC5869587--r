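aa	weight
A	0.1
R	0.4
N	-0.1
D	-0.5
C	0.2
Q	-0.1
E	-0.5
G	0.1
H	0.3
I	0.3
L	0.3
K	0.4
M	0.2
F	0.3
P	-0.4
S	0.05
T	0.05
W	0.1
Y	0.1
V	0.3
X	0
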