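variant	carriers_controls	n_controls
11606_A>G	0	120
11622_A>G	1	120
11648_G>A	0	120
15395_A>G	0	120
13635_C>T	0	120
15880_A>G	1	120
14677_T>C	0	120
15447_C>T	0	120
13630_A>G	1	120
13179_A>G	1	120
11359_T>C	0	120
13237_T>C	0	120
14748_C>T	0	120
12359_T>C	0	120
15536_A>G	0	120
13673_C>T	0	120
15558_A>G	0	120
13912_C>T	0	120
11184_C>T	0	120
13868_A>G	0	120
12608_C>T	0	120
10802_G>A	0	120
14841_T>C	0	120
11556_A>G	0	120
14211_T>C	0	120
13588_T>C	0	120
13245_C>T	0	120
12092_A>G	0	120
15623_T>C	0	120
13045_C>T	0	120
14937_C>T	2	120
15132_T>C	4	120
12871_C>T	5	120
13366_G>A	5	120
13112_C>T	3	120
14366_C>T	3	120
12140_A>G	6	120
13753_C>T	6	120
15790_G>A	4	120
15752_G>A	3	120
14520_C>T	0	120
15171_A>G	0	120
13850_C>T	0	120
15262_A>G	0	120
12083_T>C	0	120
12618_G>A	0	120
10773_C>T	0	120
11837_C>T	0	120
14579_G>A	0	120
13443_T>C	0	120
14503_A>G	0	120
14081_C>T	1	120
11892_G>A	0	120
13675_T>C	0	120
11176_C>T	0	120
14334_C>T	0	120
14665_C>T	0	120
14470_T>C	1	120
11889_C>T	0	120
15103_A>G	0	120
10883_A>G	0	120
12254_T>C	0	120
11047_A>G	0	120
13845_G>A	0	120
14529_A>G	1	120
11858_C>T	0	120
14943_T>C	0	120
12172_T>C	0	120
11878_A>G	0	120
15295_G>A	0	120
6503_T>C	0	120
7086_C>T	1	120
5966_T>C	0	120
6941_A>G	0	120
5904_A>G	0	120
5613_T>A	0	120
5771_A>G	0	120
7496_T>C	0	120
7575_T>C	0	120
15939_T>C	0	120
15912_T>C	0	120
15953_A>G	0	120
15932_T>C	0	120
15923_C>T	0	120
15933_C>T	0	120
15927_A>G	0	120
15908_T>C	0	120
15904_A>G	0	120
15921_T>C	0	120
15926_G>A	0	120
15952_C>T	0	120
15902_A>G	5	120
15947_G>A	5	120
15940_C>T	3	120
15936_A>G	5	120
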