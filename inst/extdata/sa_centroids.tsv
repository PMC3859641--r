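# Centroids of the 22-letter kappa/alpha structural alphabet on the
# (kappa, alpha) plane, in degrees, with the seven-group conformational
# classification. State Y is merged into A after assignment (merge_into).
# kappa: virtual bond angle of three consecutive C-alpha atoms, [0, 180].
# alpha: virtual dihedral of four consecutive C-alpha atoms, (-180, 180].
state	kappa	alpha	group	merge_into
A	89	50	helix
Y	91	52	helix	A
B	85	62	helix
C	96	40	helix
D	80	72	helix
G	102	28	helix-like
I	70	86	helix-like
L	112	60	helix-like
E	120	-170	strand
F	126	168	strand
H	131	-148	strand
K	106	-128	strand-like
N	141	-102	strand-like
M	46	-120	highly-curved-coil
S	51	62	highly-curved-coil
V	41	160	highly-curved-coil
W	56	-58	highly-curved-coil
Q	76	-40	moderately-curved-coil
R	90	-92	moderately-curved-coil
T	150	42	flat-coil
P	156	-62	flat-coil
X	161	148	flat-coil
Z	166	-150	flat-coil
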