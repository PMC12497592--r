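variant	score
5613_T>A	13.47
5771_A>G	14.54
7496_T>C	17.1
7575_T>C	8.58
15939_T>C	10.08
15912_T>C	4.83
15953_A>G	5.29
15932_T>C	12.17
15923_C>T	10.62
15933_C>T	8.16
15927_A>G	3.8
15908_T>C	9.16
15904_A>G	8.75
15921_T>C	12.02
15926_G>A	2.78
15952_C>T	11.38
15902_A>G	9.55
15947_G>A	5.23
15940_C>T	4.54
15936_A>G	6.08
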