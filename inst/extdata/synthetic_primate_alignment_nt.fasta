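>Homo_sapiens/5401-6000
CTCATCCAGCCCAAACGAAAGCTATCCTATCTTTGAGACTGGAAAATAGCCTACACCTCCAGCTTTTTCT
CCATAAACACCTCTGCATTCAAGCCACATATCCGCTCAAAGTGCAACTGATCCCGAAACAACAACAGCAT
CTCACTAACCTTACATAGCAACTAAACTATCATAGTAACCACAAATCATATTAAACAGAATCAACCCACT
AATATGCCCAATTAACCAAGAATCCCCCACAACTGAAACTTCCTCAGGACTCAAACCAGTACTGACTCGA
CACGGCTAAACTCCCTCATATGCTATAAATTCTTAAAATAGACACAGCCCTATCACATCCAAAGACTGAG
AGCTGACAGACCCAATTCAAAAAGTCCGACTCCAACTAGACCACACATCCAATATAACCCTCTACATGTA
CAACACCGAGCTCTAAATCCCGCATTAACCTCCCTACTACCATTCAACTACCCAGCCCAAAACACTTCTA
CTCGCCAAACTAAAGATAACCCATGCCCCCCAACGATAGCCCTTATCAGTCGCCATGTAGCTTATAAGAT
ACCAATACTACCTACATCAATTTTATGGCATTTCGTCCTA
>Pan_troglodytes
CTCATCCAGCCCAAACGAAAGCTATCTTTTC-TTGAGACTGGAAAATAGCCTACACC-CCAGCTTTTTTT
CCATAAACACCTCTGCATTCAAGCCACATTTCCGCTCAAAGTGCAACTGATCCCGAAACAACAACAGCAT
CTCACTAACCTTACATAGCAACTAAACTATCATGGCAACCACAAATCATATTAAACAGAAT-AACCCACT
AATATGCCCAATTAACAAAGAATCCCCCACAACTGAAA-TTCCTCAGGACTCAAACCAGTACTGACTCGA
CACGGCTAAACTCCCTCATATGCGATAAAT-CTTAAAATAGACACAGCCCTATCACATCCAAAGACTGAG
AGCTGACAGACCCAATTCAAAAAGTCCGACTCCAACTAGACCACACATCCAATAAAACCCTCTACATGTA
CAACACCGAGCTCTAAATCCCGCATTAACCTCC-TACTACCATTCAACTACCCAGCCCAAAACACTTCTA
CTCGCCAAACTAAAGATAACCCATGCCCCCCAACGATAGCCCTTATCAGTCGCCTTGTAGCTTATAAGAT
ACCAATACTACCTACATCAATTTTATGGCATTTCGTCCTA
>Gorilla_gorilla
CTCATCCAGCCCAAACGAAAGCTATCCCATTTTTGCGACTGGAAAATAGCGTACACCTCCAGCTTTTTCT
CCATTAACACCTCTGCATTCAAGCCACATATCCGCTCAAAGTGCAATTGATCACGAAACAACAACAGCAT
CTCACTAACCTTGCATAGCAACTAAACTATCATAGTAACCACAAATCATATTAAACAGAATCAACCCACT
GATATGCCCAATTATCCAAGAATCCCCCACAACTGAAACGTCCTCAGGACTCAAACCAGTACTGACTCGA
CACGGCTAAACTCCCTCATATGCTATAAATTCTTAAAATAGACACAGCC-TATCATATCCAAAGACTGAG
AACTGACAGACCCAATTCAAAAAGTCCGACTCCAACTAGACCACA-ATCCAATATAACCCTCTACATGTA
CAACACCGAGCTCTAAATCCCGCATTAAACTC-CTACTACCATTCAACT-CCCAGTCCAAAACACTTCTA
CTCGCCAAACTAA-GATAACCTATGCCCACCAACGATAGCCCTTATCAGTCGCCATGTAGCTTATAAGAT
ACCAAGCCAAC-TACATCAATATTATGGCATTTCGTCCTA
>Pongo_abelii
CTCATCCAGCCCAAACGAAAGCTATCCTATCTTAAAGACTGGAAAATAGCCTACACCTCAAGCTTTGTCT
CCATAAACACCTCTGCATTCAAGACGTATATCCGCTCAAAGTGCAACTGATCCCGAAACAACAACAGCAA
C-CACTAACCTTACATAGTAACTAAACTATCACGGTAACCCCAAATCATATTAAACAGAATCAGCCCACT
AATATGCCCAAATAACCAAGAATCCCCCACAACTTAAACTTCCTCAGGGCTCAAACCACTCCTGACTCGA
CACGGCTAAACTCCCTCAGATGCTATAAATTCTTAAAATAGAGACAGCCCTATCACATCCAAAGACTGGG
AGCTGACAGACCCAGTTCAAAAAGTCCGACTCCAACTAGACCACACATCCAATAT-AAGCTCTTCATGTA
CAACACCGAGCTCTAATTCCCCCATTAACCTCCCTACTACCATACAACAACCCAGCCCAGAACACTTCTA
CTCGCCAAACTAAAGATAACCCATGCCCCCCAACGATAGCCCTTATCAGTCGCCAGGTAGCTAATAAGAT
ACCATCACTACCTACATCA-TTCTATGGCATTTCGTCCTA
>Nomascus_leucogenys
CTCATCCCGTCCAAACGAAAGCTATCCTATCTTCGAGACTGCAAAATAGCCTACACCTCCAGCGTTTTCT
CCATCAACACCTCTGCATTCAAGCCGCATATACGCCCAAAGTGCAACTGATCCCGAAACGACAACAGCAT
CTCACTAACCTTAAATAGCATCTAAACTATCATAGTAACCACTAATCATATTAAAAAGACTCTACCGACT
CTCATGCCCAATTAACCAACAATACCCC-AAACTGAAACTTCCTCAGGACTCGAACCAGTACTGACTCGA
CA-GGCTAAAATCCCTCGTATGCAACAAATCCTTAAAATAGACACAGCCCTATCAGATCCAAAGACTTAG
AGCTGACAGACCCACTTCAATAAGTCCG-CTCCAACTAGACCAAACATCC-ATATCACGCT-TACA-GTA
CAACAACGAGCTCTAAATCCCGCAGTAACCTCCCTACTACAATTCAACTACCCAGACCAA-ACACTTCTA
CTTGCCAAACTATAGATAACCCATGGCCCCCAACGATAGCCCTTATCAGTCACCAATTAGCTTATGAGAT
ACCAATACTACCTACATCAATTTTATGCAATTTCGTCCTA
>Macaca_mulatta
CTCATCCAGCCGAAACGAAATCTATCTTATCTTTGAGACCGGATAATA-CCTACACCTTCAGCTTTTTCT
CCGTAAACACCTCTTCATTCAAGCCACAGATCAGCTCAAAGTTCACCTGATCCCGATACAAGAACAGCAT
ATTAATAACCTTACATAGCAATTAAACTATCACAGTAAACACAAAACATACTTGACAGAA-AAATCCACT
AATATGCCCAATTAACCAAGAGTCCCGCACAACTGAAACTTCCTCAGGACTCTGACCAGTACTGACTCGT
CATGTCTAAACTCCCTCATAT-CTAGAAATTCTCGAATCAGACATAGCCGGTTCACATGGACAGACTGAG
AGCCTACAGACCCAATGCAAAAAGTCCGACTCCAACTAGACCACACATCCAATATAACCCTCTACA-GTA
CAACACGGAGCTATTAATCCCGCTTCAAACTCCC-ACTAGCATTCACCTACCCGGCCCTAAAGACTCTTA
CTCGCCAATCTAAAGATAACTCCTGGCCCCCCACGATAGTCCTTCTCACTAGACATGTAGATTCTAAGAT
ACCAATACTAACTACATCAATTTTATGGCATTTCGTCTTA
>Papio_anubis
CTCATCCAGCACAAACGAATGCTATCCTATCTTGGGAACTGGAAAATAGCCGACACTTCCAGCTTTTTGT
CCGTAAACACCCCTGCATTCGAGCCACTTATCCGCTCAAAGTGCGACTGATCACGAATCA-CACCAGCGT
CTCACTAACCTTACACAGCAGCTAACCTATCATAGTAACCACAAATCATATTAGACAGAATCAACCCACT
AATACGCCCTTTTAACCAATAATCACACCCAAATGAAACCCCCTCGGGACTCAAACCCGTACTGATTC-A
GACGGCTAAACTCCCTCATATGCTATAAATGCTTAAAGCAGACACATCCCTATCACATCCAAACAATGAG
AGCTGACCGACTCAATTCAATTAGTCCCACTACAACTAGACCAACCAGCCAATATAACCCTCTACATGTA
GCACACCCGG-T-CAAAACCCGCTTTAACCTCCCTACTACCATCCAACTATCTAGCCCACAACACTTTTA
CTCGGCAAACGAAAGATAACTCATGC-TCCCGACTCTTGCCCTTATGAGTCGCCATGTAACTAATAAGAT
ACCAATACTAGCTACATTAATTTTATGGCATTTCGTCCTA
>Callithrix_jacchus
CTCATCCAGCAC-AACGAAAGCTATCGTCTCTTTGAGACTGGGACCTAGCCTAGACCTCCAGCCTTTTCT
CAAGACGCTCCTCTGCATTGATGACACATATCCCCTCAAAGGACGACTG-TCCCGAAACACCAACAGCAC
CTAAC-AACCTTACATAGCAACTAAAGTA-GATAGTAACCAAAAATCATTTCGAGCAGCACCAACCCACG
ATTATGTCTGATTAACCGG-TATCCCCCACAACTGAAACTTCCTCAGGAC-CAGACCAGTGCT-ACTC-A
CACGCTTATACTCCATCATATGCTATAAATTCTGAACAAAGCTACAGCCCTATCTCACCCCAAGGGTGAG
AGCTGACCTGCCCAATTCCAAAAGTCTAACTTCAACTCGGGGACACGTCCAA-AAAACCCCCTACATGCA
CAAGAACAGGCTCTAAGTCCGGCTTTAAC-TCCCTACTACCATTCAGCGACCGGGCCGAACATACTTTTA
CTCGCCCAACTAACTATAACCCATGTCCCACAACGATAGCCCTTATCCGTCGCCATGTCACTTAGCAGAG
ACCATTGCTACCTTTAGGGATTTCATTGGATTTTGTCCTG
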