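# Position-specific boundary preference table estimated from the default
# synthetic beta-barrel corpus (101 proteins, seed 20260925). Synthetic
# stand-in for a table derived from real structurally resolved proteins.
amino_acid	score_N	score_C
A	1.49702139924485	-0.983738643771012
C	-0.772735559973569	-1.66853310226828
D	-2.2858106200087	-0.137214042944957
E	-2.26416530133798	0.161965251254676
F	4.81578429017336	1.70349492798189
G	-2.68743282187858	0.198129349351376
H	-1.05143512250539	0.753207053340997
I	3.07743048656839	0.0224343494244272
K	-3.29295415546569	0.168800306857687
L	2.48967773359977	-0.0640138318699414
M	2.65963245471105	-0.6512025868625
N	-1.89173893204302	0.271357214715845
P	-1.37012951837658	-4.26592706067129
Q	-3.07407116140768	0.239584661926566
R	-1.76204415572849	0.149513224034406
S	-3.81448749404218	0.377177804913455
T	-2.51487971588557	0.759247743262038
V	2.85107640508197	-0.356665143527479
W	4.73501675156058	1.70632493876853
Y	4.65624503771345	1.61605758608357
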