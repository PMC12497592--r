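haplogroup	parent	defining_variants
mt-MRCA		
L3	mt-MRCA	769_G>A,1018_G>A
N	L3	8701_A>G,9540_T>C,10398_A>G
M	L3	489_T>C,10400_C>T,14783_T>C
A	N	1736_A>G,4248_T>C,4824_A>G,8794_C>T
A15	A	64_C>T,2245_A>G,6620_T>C
N9	N	5417_G>A,12358_A>G
N9a	N9	12372_G>A,16257_C>A,16261_C>T
Y1	N9	7933_A>G,8508_A>G,14178_T>C
R	N	12705_C>T,16223_C>T
B4	R	16217_T>C,5465_T>C,9123_G>A
B4a	B4	6719_T>C,9852_T>C,15346_G>A
B5	B4	709_G>A,8584_G>A,9950_T>C
R9	R	3970_C>T,13928_G>C
F1	R9	6962_G>A,10310_G>A,12406_G>A,12882_C>T
F2	R9	10535_C>T,13708_G>A,16291_C>T
R11	R	1095_T>C,14502_T>C,16304_T>C
D	M	1824_T>C,1842_A>G,5178_C>A
D4	D	3010_G>A,4883_C>T,8414_C>T,14668_C>T
D4a	D4	3206_C>T,8473_T>C,14979_T>C
D4b	D4	8020_G>A,15440_T>C,15951_A>G
D5	D	752_C>T,1107_T>C,5301_A>G,10397_A>G
D5a	D5	7269_G>A,11944_T>C
G	M	4833_A>G,8200_T>C,14569_G>A
G2	G	7600_G>A,13563_A>G
M7	M	6455_C>T,9824_T>C
M7a	M7	2772_C>T,11017_T>C,12771_G>A
M7b	M7	4071_C>T,6680_T>C,12811_T>C,16297_T>C
M8	M	4715_A>G,15487_A>T
Z	M8	6752_A>G,9090_T>C,15784_T>C
Z3	Z	16185_C>T,7521_G>A
M10	M	8793_T>C,10646_G>A,13152_A>G
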