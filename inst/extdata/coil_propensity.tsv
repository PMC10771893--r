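# Synthetic single-residue heptad propensity table (log-odds per residue and
# heptad position a-g). Hand-constructed from the qualitative architecture of
# canonical coiled coils: hydrophobic residues favored at the core a/d
# positions, charged residues at the flanking e/g positions, mild preferences
# at b/c/f, helix breakers (G, P) penalized everywhere. Not derived from any
# external training set.
# window: 28
# threshold: 21
# unknown_score: min
aa	a	b	c	d	e	f	g
A	0.9	0.3	0.3	0.8	0.2	0.3	0.2
R	-0.4	0.5	0.4	-0.5	0.7	0.4	0.6
N	-0.6	0.3	0.3	-0.6	0.2	0.3	0.2
D	-0.9	0.2	0.3	-0.9	0.3	0.3	0.1
C	0.2	-0.2	-0.2	0.2	-0.3	-0.2	-0.3
Q	-0.2	0.5	0.5	-0.2	0.8	0.5	0.7
E	-0.6	0.6	0.6	-0.6	1.2	0.6	1.0
G	-2.0	-1.0	-1.0	-2.0	-1.0	-1.0	-1.0
H	-0.4	0.0	0.0	-0.4	0.0	0.0	0.0
I	1.8	-0.3	-0.3	1.4	-0.3	-0.3	-0.3
L	2.2	-0.2	-0.2	2.0	-0.2	-0.2	-0.2
K	-0.5	0.6	0.5	-0.5	1.0	0.5	0.9
M	1.3	0.0	0.0	1.0	0.0	0.0	0.0
F	0.5	-0.5	-0.5	0.4	-0.5	-0.5	-0.5
P	-3.0	-3.0	-3.0	-3.0	-3.0	-3.0	-3.0
S	-0.3	0.2	0.2	-0.3	0.1	0.2	0.1
T	-0.2	0.1	0.1	-0.2	0.0	0.1	0.0
W	0.1	-0.6	-0.6	0.1	-0.6	-0.6	-0.6
Y	0.0	-0.4	-0.4	0.0	-0.4	-0.4	-0.4
V	1.5	-0.4	-0.4	1.1	-0.4	-0.4	-0.4
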