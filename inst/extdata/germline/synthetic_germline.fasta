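>IGHV1-18*04
TTTTTTAGTACCCCTCCCCACGGCAATTCTCGAGTGGATGTGACTTCGACCATTCACTATCAGCCGTCCTTTGAATCACATAGATTCTGTTCGCATGACACCTGTAAGCTGCTGGTCGTGGATCTTAGCCCGGTAAGCAGTACACGGGGCAAGCCTCGATCTACAGGCAGCAATTCACGACGTTCAAATTACTTAGGACACATGAAAAGAGGTCTTGCGGCGTTCACTCATGAGGCCTTGGGTCCAAATAAGTCGCCCGTGTACATGTCAATGGTAGAGCGTATAGATTGTCCCTTCGAC
>IGHV1-69*01
GGTCGGCTTCAGGAACGTATGATAGCTGCTAGTGACGCTTGGCGGTGGCCGGCGGCTTGGTTCGTGCGCTCTCCCAGGGGCCCACTTACCGGGACGAAGTTTGCCTTTAGGAACTCTGCAAACAAGTCAGGAGACGAGGGCACTAAGTACGGGAGTCATCGACCACTAGTCTCTACAACGTTAATTACCGTGCGATACTGCAGGCACCTTGGCCAACATACACGGATAAAAAATTCGCGGAACAGCACAAAACGCAAACTCACCTGGAGCAGTCGAACTAACGCACAGTGTAACCAGGGC
>IGHV3-23*01
CTGGAGTTGGCTTACTATATTTTTTCGTACTCTGAAAAACTGGAGGCTGCCCTCAGTGCAGTCCTATACTGGAGCCTGGTGGGCTTGCAAATTGCCTTTCAGTTACTTTTTGAGATGCTCGCCGTCCTAGCAGCCCTGAGCATAGCCCCAAATAATTGGATTATTACTAGTTTGACCGGCCCCAGAAAGCCAAGACATCAAATGCGCGCGTGTGGGAAATATAGTCCGATCCCGAATCATGCAGGTACGTTGTCCCGGTTTTCGAGAAGTCATCAGGGGCCGCATGAATGTGCGAGTTAT
>IGHV4-39*01
GAAGTCATATACACTGGCTTCCTTGAGTCCAGAGCACGGTGGGATCTCACCAGTCAGCACAATGTAGACAATTTAGATGTAGATTGCCGGAAGCATATGCATCGTGATGGGTATAACTACGTGCATGCAGCGAACGACGCATCTAAGTACACACCCGAGCATCAAGACACTAGATATTCGTTATTGACGGTGGGCCGGGCATTATCGATGCCTGCTCGGCGCTATCCATCCACAATCTACATCCACAGCGTCGGTCCCAGATGGACAGCCACACTCAGCGTCACACCATGTATCTATAAG
>IGHV5-51*01
AACGCTGTATGCACTCTTGCGGGAGAGCCCGATCCCGGATGCTACACCCGTGCATTACGCATAAGGGCTCTTCAACAGCCAGCACTCGAGTTGGGTCACGCTCAGTTGCCCCTAGAAGCTGTCGAGGGTATCTTGGAGTGGTTAGGCAATACAAAGTTATATGACCATATTCCTGATGCCGTGTCTGATTATGTTCCTCCGGATTTAGTTGCTCCGACTTATTCTTCGCGCGCGTTCTCATTCTCTATCAAATTAATATGTGCAAGGAGTTTAGCGACAATCCCGAGCTGTGGCACTAAC
>IGHD1-26*01
AGCGACTAGGTCAAT
>IGHD2-2*03
GTCTCCCCAAGCGCA
>IGHD2-8*01
ACGTCCTCGCACCAG
>IGHD3-10*01
CTCAAACGCCGAAGC
>IGHD6-6*01
CCAGGTTATCGGCCC
>IGHJ3*02
TTAGCCAGTAGCGCCTTGGTGTGGGGCATTGGGGAATCATGCCTGGTG
>IGHJ4*02
CCCCGTGGACTTTTTGCCGGCTGGGGCACTGGGTGGTTTATAATCTCG
>IGHJ5*02
TCCAGGAATTTTGAAGTTGTCTGGGGCAAGGGGCGTTCACTAAGTCTG
>IGHJ6*02
GGCCACTAGACCGTCAGAGAGTGGGGCGGCGGGGTAAAGTACCTATCT
>IGKV1-39*01
ATCTGTGATCTATTATTTTTCGAAGCTCATATGCACGAACTATTTTCTACACTTGATTTTATTACGCAGGCATCACGATGTGCGGACATGGAATCCCGGATTCAGTTACGTAACTCCTCCCGCTCGACCGGCAACCTCTGCTCGGGAGGAATACGGAGGATTGTATCAACTCGAGGGCCGTCACACGGCCCGGTATTATTTGTTGTGAAAACTCCGGGAGATATCCATGAAGTCCGGGGCGAGACATGGTCGGGGTCGATCCTAGAGCTAGCCGCCAGTTTCCAACTGTGTGTGCGGAGT
>IGKV2-28*01
ACCTCGCTCACAAATAGTCGTCAGGTTCTGGAGTTACCGTTGCAGAGTGTCCGTAATGTCTATACCGAAATTCTGGGGCCCGTTCCCTTAGACATCTCCCTTCGAACATTACAGGTCCGGCCGAAATTTAAAGGATCTGTCGAGGATGCATTTGACGCTGGTGGAAGGCGGGAGTCGTATTTGAGAACAATTGGAGAAGGTAGTATAAGTCCGGCGTACTTTACTCACGTAATAGTAGAAGGACTTATCCGGGTGCCAATCATTGAATATAGTATGATGGCGGCCCCGTGTACGCGAGAG
>IGKV3-20*01
AACGGGGAGATGCCCTTCGTTGTTCACGCTTTAAGAGATTGTCCGCGGATTAGTTGCAACGTATTGATCCTGTTATCTGCCATAGGAGTGGGCGGGCCGCCCGATCTTGTTTGGGATACGTTCCCCTTCCTCATGTGCGTTCCAAGCGACCGTTGCTTAGATGGTTTACCACAGTCTAATTCCGCTGCCGGTTGCAACTCAACCCAGTTAGAAACGGCTCACGGCTGCTCAAATTCACATTCTCCACACAGCTGGTATTTCCGTGCGCCTCTACACAAAATCTTAGCGTGTTGCAGGACT
>IGKV4-1*01
GTGACTTGCATGGACCTTGCTGATGCGCCTTTCGTTTTATTGGGCCGTGCAGTGCACCACAACCTATCAAGTCGGACCACTAACAAATTACCAATCCGCGTTGGACATGGTGTGCTGGGCCTACCGGTTGGCCGGCACAGACTCGAAGTCAACCAGGTTCTTCCGGCCCAGGGGGTAGGCGCTTGCGAGTTTATACAGCTGGTAAGGCGAATTCCCGTCCAGGTTATCAAATGTAATAACGTTACCTCCTTTCACTTCTCACTGGAACGCGTATGTTATAACATCGGTTGTCTTTGCACC
>IGKJ1*01
CGGCCAGACGATCGGCGGACGTTCGGCTGTGGGCATTCTATCCGCGTT
>IGKJ2*01
ACTAGGCGATGTCAGCCCTCTTTCGGCAAGGGGGGAGTTGAGTTCCTG
>IGKJ4*01
TGAAGACTCAAAGCACACGTATTCGGCTCAGGGCAAACAACGTTGAGT
>IGLV1-40*01
TACCCGAATCGGCCTTATGAAACGGTACAGAGACGATTCTTATCTCGAAGTTGGAGGTTGTGGGTCTGTAGTACAATCTTCTGCCCTCTTTATGGGGGCCATAGTTACTGGGCTGGCTATCGATTCAAGCCTTGGAAATGTTTGCGACGGCAGACGCGATTACCAACGGGAACTCTCACACGCCTGGTCGGTGACGCATGGGACGGTAAAATGGCGGTATCGAAGCCACCGTGCCACGAAAGGGTGCTCGTGATGCACTCTAAACCTGTCAGCCCGCGGTCTACATACTGTGTTGGAGTG
>IGLV1-40*02
TACCCGAATCGGCCTTATGAAACGGTACAGAGACGATTCTTATCTCGAAATTGGAGGTTGTGGGTCTGTAGTACAATCTTCTGCCCTCTTTATGGGGGCCATAGTTACTGGGCTGGCTATCGATTCAAGCCTTGGAAATGTTTGCGACGGGAGACGCGATTACCAACGGGAACTCTCACACGCCTGGTCGGTGACGCATGGGACGGTAAAATGGCGGTATCGAAGCCACCGTGCCACGAAAGGGTGCTCGTGATGCACTCTAAACCTGTCAGCCCGCGGTCTACATACTGTGTTGGAGTG
>IGLV1-44*01
CTAGACCGCACAGAGACGCCGATGCTCCTTAATCGCGACAATTTGACCAAAGTCTACAACAGTATCCCGAACACGAGTAAGCCGCCTTCAGTGAATAGGCTCGTATTGTACATATTTTTAAACTGTGTCTCCAGCGTGTGCAGCACATGTCGCGGCGTGTTGTTGTTCCGTGCTTCTTGGCTCGTTTACCCTTGGATCGCAGCCTCGCGTACGAACCGTCGGCCCGACCCGGTTTTTCCTGTTAACGGCGGATCGGAACAGAACATCCGTGCCGACTCACAAAAAACCTGTACTCCCACC
>IGLV2-11*01
CAACATGGCCGTCCCAGCACAATCCTACCGTGGTCACGACTAAGATGTGGGCTTTCGGGAGGCCTGGCAGCCCCCTTTATTCAGGGCCTTGCATTAACCGTCAGACCCTGCTGCGACCGCGCTTGCATACTCCCTCTAGATCACATACGATCAAGTGCACAGATGAGATTTCGTCGAAAGCACTCTCTCTTGAGGCCTGCGGGCACGCTAGGCGAAGGGTCCCCCATTGACAAGGTCGACGCGGGCAGGGAGTCTGTGAAAAACAACGCGGCCTTTCAGTTCCACGCATGTACAGGGACG
>IGLV2-14*01
CAGGACTCGAGATTCTCAGCTTCAAAGGTATTTACGTCGTTCCCAAAAAGCGGTTATGTTGTCTATTACGTTAGCAGTAAGGAGTGTTATGGAACCGAGCGTAGGCGCTCTCATAGTCTCCACATGGGGACACCTCGCAATCCCTCCGCTTGCAGTACTACCGAGTCACCACATACAGTTACCCCGACATCGGGCGTCCAAACGTTAATCCGTCGCTTGGTCGAAATTCCACCACCGCTCTCTTTTAAGCAACACTCCCCGATTGCAACAGCTTCTGACCTTGCAACGTGTGCGACCGTC
>IGLJ1*01
GACATCGGTGTGCATGGTAGATTCGGCGGCGGGGTACGTGGCCCACCG
>IGLJ2*01
CGTGCTGTGCCCCATATGTCGTTCGGCTGCGGGGGTAGCGGTTCTATG
>IGLJ3*01
TGTCACTACTGGGGCTAAGCGTTCGGCGTAGGGGAGGATACTAAAGAA
>IGLJ3*02
CGCCATCCCTTATCGGATGTATTCGGCATCGGGGCTATGCCCATGCAT
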