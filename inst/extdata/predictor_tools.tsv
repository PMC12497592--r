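tool	threshold	direction
PolyPhen2	0.85	higher
SIFT	0.05	lower
VEST	0.5	higher
Mitoclass.1	0.5	higher
SNPdryad	0.5	higher
AlphaMissense	0.564	higher
CADD	20	higher
PROVEAN	-2.5	lower
MutationAssessor	1.9	higher
EFIN	0.6	higher
MLC	0.7	higher
PANTHER	0.5	higher
FatHmm	-0.75	lower
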