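variant	region	coding_effect
11606_A>G	protein	nonsynonymous
11622_A>G	protein	nonsynonymous
11648_G>A	protein	nonsynonymous
15395_A>G	protein	nonsynonymous
13635_C>T	protein	nonsynonymous
15880_A>G	protein	nonsynonymous
14677_T>C	protein	nonsynonymous
15447_C>T	protein	nonsynonymous
13630_A>G	protein	nonsynonymous
13179_A>G	protein	nonsynonymous
11359_T>C	protein	nonsynonymous
13237_T>C	protein	nonsynonymous
14748_C>T	protein	nonsynonymous
12359_T>C	protein	nonsynonymous
15536_A>G	protein	nonsynonymous
13673_C>T	protein	nonsynonymous
15558_A>G	protein	nonsynonymous
13912_C>T	protein	nonsynonymous
11184_C>T	protein	nonsynonymous
13868_A>G	protein	nonsynonymous
12608_C>T	protein	nonsynonymous
10802_G>A	protein	nonsynonymous
14841_T>C	protein	nonsynonymous
11556_A>G	protein	nonsynonymous
14211_T>C	protein	nonsynonymous
13588_T>C	protein	nonsynonymous
13245_C>T	protein	nonsynonymous
12092_A>G	protein	nonsynonymous
15623_T>C	protein	nonsynonymous
13045_C>T	protein	nonsynonymous
14937_C>T	protein	nonsynonymous
15132_T>C	protein	nonsynonymous
12871_C>T	protein	nonsynonymous
13366_G>A	protein	nonsynonymous
13112_C>T	protein	nonsynonymous
14366_C>T	protein	nonsynonymous
12140_A>G	protein	nonsynonymous
13753_C>T	protein	nonsynonymous
15790_G>A	protein	nonsynonymous
15752_G>A	protein	nonsynonymous
14520_C>T	protein	nonsynonymous
15171_A>G	protein	nonsynonymous
13850_C>T	protein	nonsynonymous
15262_A>G	protein	nonsynonymous
12083_T>C	protein	nonsynonymous
12618_G>A	protein	nonsynonymous
10773_C>T	protein	nonsynonymous
11837_C>T	protein	nonsynonymous
14579_G>A	protein	nonsynonymous
13443_T>C	protein	nonsynonymous
14503_A>G	protein	nonsynonymous
14081_C>T	protein	nonsynonymous
11892_G>A	protein	nonsynonymous
13675_T>C	protein	nonsynonymous
11176_C>T	protein	nonsynonymous
14334_C>T	protein	nonsynonymous
14665_C>T	protein	nonsynonymous
14470_T>C	protein	nonsynonymous
11889_C>T	protein	nonsynonymous
15103_A>G	protein	nonsynonymous
10883_A>G	protein	nonsynonymous
12254_T>C	protein	nonsynonymous
11047_A>G	protein	nonsynonymous
13845_G>A	protein	nonsynonymous
14529_A>G	protein	nonsynonymous
11858_C>T	protein	nonsynonymous
14943_T>C	protein	nonsynonymous
12172_T>C	protein	nonsynonymous
11878_A>G	protein	nonsynonymous
15295_G>A	protein	nonsynonymous
6503_T>C	protein	synonymous
7086_C>T	protein	synonymous
5966_T>C	protein	synonymous
6941_A>G	protein	synonymous
5904_A>G	protein	synonymous
5613_T>A	tRNA	noncoding
5771_A>G	tRNA	noncoding
7496_T>C	tRNA	noncoding
7575_T>C	tRNA	noncoding
15939_T>C	tRNA	noncoding
15912_T>C	tRNA	noncoding
15953_A>G	tRNA	noncoding
15932_T>C	tRNA	noncoding
15923_C>T	tRNA	noncoding
15933_C>T	tRNA	noncoding
15927_A>G	tRNA	noncoding
15908_T>C	tRNA	noncoding
15904_A>G	tRNA	noncoding
15921_T>C	tRNA	noncoding
15926_G>A	tRNA	noncoding
15952_C>T	tRNA	noncoding
15902_A>G	tRNA	noncoding
15947_G>A	tRNA	noncoding
15940_C>T	tRNA	noncoding
15936_A>G	tRNA	noncoding
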