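symbol	score
A	295.15
C	226.38
D	244.80
E	272.83
F	243.43
G	225.08
H	317.03
I	247.03
K	296.78
L	288.23
M	311.58
N	232.70
P	276.55
Q	198.45
R	229.63
S	268.65
T	242.05
V	212.55
W	328.60
Y	355.55
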