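variant	ci
11606_A>G	0.8546
11622_A>G	0.9048
11648_G>A	0.8858
15395_A>G	0.7735
13635_C>T	0.794
15880_A>G	0.9259
14677_T>C	0.8308
15447_C>T	0.8226
13630_A>G	0.969
13179_A>G	0.7855
11359_T>C	0.7669
13237_T>C	0.8276
14748_C>T	0.9537
12359_T>C	0.8274
15536_A>G	0.9971
13673_C>T	0.8244
15558_A>G	0.8637
13912_C>T	0.7971
11184_C>T	0.7954
13868_A>G	0.762
12608_C>T	0.7747
10802_G>A	0.879
14841_T>C	0.8982
11556_A>G	0.966
14211_T>C	0.9527
13588_T>C	0.9899
13245_C>T	0.8315
12092_A>G	0.8697
15623_T>C	0.831
13045_C>T	0.802
14937_C>T	0.8697
15132_T>C	0.9586
12871_C>T	0.8273
13366_G>A	0.9844
13112_C>T	0.798
14366_C>T	0.9101
12140_A>G	0.8354
13753_C>T	0.8621
15790_G>A	0.9047
15752_G>A	0.965
14520_C>T	0.7299
15171_A>G	0.4993
13850_C>T	0.4188
15262_A>G	0.4836
12083_T>C	0.4631
12618_G>A	0.7874
10773_C>T	0.8102
11837_C>T	0.8725
14579_G>A	0.783
13443_T>C	0.9882
14503_A>G	0.8932
14081_C>T	0.9496
11892_G>A	0.9903
13675_T>C	0.984
11176_C>T	0.9185
14334_C>T	0.9766
14665_C>T	0.9834
14470_T>C	0.7807
11889_C>T	0.7796
15103_A>G	0.8112
10883_A>G	0.8427
12254_T>C	0.9592
11047_A>G	0.9372
13845_G>A	0.9114
14529_A>G	0.7884
11858_C>T	0.909
14943_T>C	0.8053
12172_T>C	0.9958
11878_A>G	0.8333
15295_G>A	0.8792
6503_T>C	0.9738
7086_C>T	0.9908
5966_T>C	0.9988
6941_A>G	0.9654
5904_A>G	0.8271
5613_T>A	0.9232
5771_A>G	0.9875
7496_T>C	0.8136
7575_T>C	0.8752
15939_T>C	0.8756
15912_T>C	0.8486
15953_A>G	0.768
15932_T>C	0.8256
15923_C>T	0.9836
15933_C>T	0.8163
15927_A>G	0.9358
15908_T>C	0.9382
15904_A>G	0.8516
15921_T>C	0.8083
15926_G>A	0.7228
15952_C>T	0.4192
15902_A>G	0.8037
15947_G>A	0.8359
15940_C>T	0.9717
15936_A>G	0.8899
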