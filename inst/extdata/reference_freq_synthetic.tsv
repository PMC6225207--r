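# synthetic reference residue frequencies (not measured data)
A	0.0606060606
C	0.0432900433
D	0.0432900433
E	0.0606060606
F	0.0432900433
G	0.0562770563
H	0.0432900433
I	0.0432900433
K	0.0476190476
L	0.0865800866
M	0.0432900433
N	0.0432900433
P	0.0432900433
Q	0.0432900433
R	0.0432900433
S	0.0735930736
T	0.0432900433
V	0.0519480519
W	0.0432900433
Y	0.0432900433
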