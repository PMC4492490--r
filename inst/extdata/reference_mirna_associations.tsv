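mirna	chrom	start	cn_fdr	target_fdr
hsa-mir-20a	13q	90801327	0.000	0.000
hsa-mir-92a-1	13q	90801618	0.000	n.d.
hsa-mir-17	13q	90800874	0.000	0.001
hsa-mir-15a	13q	49521268	0.000	0.010
hsa-mir-19a	13q	90801194	0.001	0.052
hsa-mir-19b-1	13q	90801463	0.002	n.d.
hsa-mir-16-1	13q	49521123	0.160	n.d.
hsa-mir-18a	13q	90801011	0.255	0.017
hsa-mir-320d-1	13q	40199964	0.360	n.d.
hsa-mir-622	13q	89681504	0.428	0.633
hsa-mir-623	13q	98806372	0.779	0.050
hsa-mir-1297	13q	53784118	0.807	0.984
hsa-mir-1267	13q	106981565	0.964	0.989
hsa-mir-621	13q	40282935	0.969	0.906
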