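# Base-pair formation probabilities in rRNA 3D structures (canonical and
# non-canonical), per unordered nucleotide pair. Dimensionless, range [0,1].
base1	base2	prob
A	A	0.0519
A	C	0.0870
A	G	0.1566
A	U	0.4965
C	C	0.0189
C	G	0.6979
C	U	0.0473
G	G	0.0303
G	U	0.1210
U	U	0.0455
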