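gene	chrom	p	sign
TYRO3	15q	0.001	negative
UCP2	11q	0.001	negative
RNF125	18q	0.001	positive
RASGEF1B	4q	0.008	negative
COPS2	15q	0.010	negative
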