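"population","A","B","D4","D5","F","G","M7","R","Z","Others"
"N_Sichuan",0.0921,0.1574,0.1405,0.0578,0.1862,0.081,0.1005,0.074,0.0456,0.0649
"Chaoshan",0.0704,0.2154,0.1119,0.0448,0.1731,0.0408,0.1647,0.0686,0.0255,0.0848
"Yunnan",0.0898,0.1444,0.1513,0.0461,0.1893,0.0745,0.1144,0.0879,0.0368,0.0655
"Guizhou",0.0885,0.1575,0.138,0.0587,0.1917,0.0788,0.1062,0.0843,0.0364,0.0599
"Fujian",0.0549,0.2015,0.1197,0.0517,0.1648,0.0532,0.1497,0.0775,0.0379,0.0891
"Taiwan",0.0629,0.2091,0.1092,0.0551,0.1626,0.043,0.1647,0.0742,0.0304,0.0888
"Guangdong",0.0655,0.192,0.1228,0.0482,0.161,0.0546,0.148,0.0779,0.038,0.092
"Henan",0.0813,0.1538,0.1848,0.0533,0.1437,0.0789,0.0901,0.0863,0.0553,0.0725
"Hebei",0.079,0.1512,0.1715,0.0587,0.153,0.0773,0.11,0.084,0.0436,0.0717
"Shandong",0.0945,0.136,0.1997,0.0589,0.1404,0.0897,0.0775,0.0739,0.0574,0.0720000000000001
"Shanxi",0.0842,0.1474,0.1834,0.0594,0.1445,0.0863,0.0888,0.0738,0.0574,0.0748
"Shaanxi",0.0846,0.1411,0.1783,0.0652,0.1382,0.0903,0.0958,0.0774,0.0575,0.0716
"Gansu",0.1019,0.135,0.1833,0.0529,0.1306,0.0846,0.0875,0.0806,0.0569,0.0867
"Qinghai",0.0867,0.1413,0.1895,0.0629,0.1485,0.094,0.0872,0.073,0.0472,0.0697
"Xinjiang",0.0788,0.1446,0.1772,0.0655,0.144,0.076,0.0891,0.0877,0.0561,0.081
"Hunan",0.0936,0.1455,0.1788,0.0598,0.1382,0.0883,0.0968,0.0771,0.0464,0.0755
"Hubei",0.0816,0.1413,0.1726,0.0567,0.1504,0.0873,0.0918,0.0834,0.0574,0.0775
"Jiangsu",0.0926,0.1388,0.1749,0.0613,0.1432,0.0738,0.095,0.087,0.0501,0.0833
"Zhejiang",0.0842,0.1389,0.189,0.0573,0.1481,0.0812,0.0868,0.0852,0.0563,0.073
"Anhui",0.1005,0.1348,0.1879,0.0625,0.1405,0.0891,0.0893,0.0732,0.0501,0.0720999999999999
"Jiangxi",0.0843,0.1402,0.1895,0.0607,0.1399,0.0802,0.0849,0.0784,0.0581,0.0838
"Liaoning",0.0828,0.1512,0.1732,0.0547,0.1541,0.088,0.097,0.0733,0.0567,0.0690000000000001
"Sichuan",0.0823,0.1541,0.157,0.054,0.1786,0.076,0.0986,0.0844,0.0415,0.0735
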