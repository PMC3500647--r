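>V01
CGGCCCCTGTGTCCAAGTACAACTCAGAGAATCCGGGCCATCGCTAGTAAAGCCATCACAGACCTTGAGTCTGACTTGCA
CTGCTTCCGGTTTCTCTCTCAGCAGTCGTACCGTGGCGTGGGTGAGACAAGCTCCAGGTAAAGCACTTGAGTGGGGAATT
ACGGGCGCGCGCGGAACAACTTACAAGGCAACGCGGTTTACAATCAGCAGAGATAATAGTAAAAATACACTCTATCTTCA
GATGAATAGCTTACGAGCGGAAGACACGGGGGTGGCCACATATTACTGTGCGAAA
>V02
CGTCGCTCAAGTTCAGCTGCGTGAGTCTGGACCGTCCCTCGTCAAACCGAGTCAAACCCTTTCGCTAACGTGCACTGCCT
CTGGGTTTTCCTTAAGTTTCAATGGCGTGAACTGGGTAAGGCAGGCGCCCGGGAAGGCGCTAGAATGGGGGATTAACAAT
TGGGCTAGGACTGATTACGATGCAACTCGGTTCACCATCTCTCGTGATAACTCCAAGAACACGTTATATCTTCAAATGAA
TTCACTCCGTGCCGAAGATACAGGTGTCGCGACTTACTATTGTGCCCGG
>V03
TTCTGGAACCTGGGCACAAGTGCAGTTGCGCGAGAGCGGACCGAGCCTTGTAAAGCCCAGCCAAACCCTGTCGCTAACTT
GTACAGCTTCAGGGTTTTCGCTATCGCACCATTTCGTCTTTTGGGTGAGACAGGCCCCGGGGAAGGCACTAGAGTGGGGG
ATCCGTGACTGGCGTAATACCGATTATGACGCCGCAAGGTTTACAATTTCGCGCGATAATTCTAAAAATACCCTCTACCT
GCAGATGAACTCCCTTAGAGCTGAGGACACCGGCGTCGCAACATATTATTGCGCTACC
>V04
GGGTACCCGTTTGGATGCAAGTTCAACTCCGTGAGAGTGGGCCGTCTCTAGTGAAACCATCACAAACTCTAAGCTTAACT
TGCACCGCATCTGGGTTCTCATTGTCCCACGCCTCAGTCGGTTGGGTTCGGCAAGCGCCCGGGAAAGCGTTAGAGTGGGG
GATCGCCAACTGGGGCTACACGAAGTACGGAGCTTATCGTTTCACTATCTCTCGCGACAACTCAAAGAATACCTTATATC
TGCAGATGAACTCCCTCCGTGCAGAAGATACTGGAGTTGCAACGTATTATTGCGCACGA
>V05
CATGAGTACTCAGGTTCAATTGCGCGAGAGTGGCCCTTCTCTTGTTAAACCGTCACAGACTTTAAGTCTCACCTGTACTG
CGAGTGGGTTCAGCCTATCACATACATACGTTGATTGGGTGCGACAAGCTCCCGGCAAGGCGTTAGAATGGGGAATTGAT
AAAAAAGGTGGTACAGCGTATAAAGCAAAACGGTTCACTATCTCACGTGACAATAGCAAGAACACCCTATACTTGCAAAT
GAATTCGTTGAGGGCGGAAGATACTGGAGTTGCGACGTATTATTGCGCTCGG
>V06
CCACGAGTCAGGTGCAGTTGAGAGAATCGGGCCCTTCCCTTGTCAAACCTAGCCAAACGCTCTCGCTAACCTGCACTGCT
TCAGGATTCTCATTGTCTAGGCACGCAGTAGCGTGGGTACGGCAGGCACCCGGCAAGGCACTGGAATGGGGAATAGACAC
AACCAACTGGACAGCGTACGGTGCTAACAGGTTCACAATATCGAGAGACAATTCAAAGAACACGCTATACTTACAGATGA
ACAGCTTACGAGCGGAGGACACAGGGGTTGCAACATACTACTGCGCGCGT
>V07
CAGCATGCGGGACGCAAGTCCAACTTAGAGAGAGCGGACCATCTTTAGTCAAACCATCACAAACCTTAAGCCTGACATGT
ACCGCAAGTGGCTTCTCTCTAAGTGGCGACGACGTCGACTGGGTTCGGCAGGCCCCCGGCAAAGCTTTGGAGTGGGGTAT
CACATGGAAAAATAGTACTGATTATAAAGCGGATAGATTTACGATTAGTAGGGATAACTCCAAAAATACACTCTATTTGC
AGATGAACAGTCTTCGCGCAGAAGATACCGGTGTTGCAACATATTACTGCGCGACG
>V08
ACGGTTACGGTCGTCCAGGTGCAGTTGCGGGAAAGTGGCCCCTCCTTGGTAAAACCCTCGCAAACACTAAGTCTCACTTG
TACCGCTTCAGGATTCTCCTTGTCTTATCGTCACGTAGGGTGGGTTAGACAAGCTCCCGGTAAAGCGCTTGAGTGGGGCA
TAGGACGGAAGAACGGAACCAGCTATGACGCATATCGGTTTACGATATCAAGGGATAACAGTAAGAACACGTTATATCTA
CAAATGAACTCGCTTCGAGCCGAAGACACGGGTGTCGCAACCTACTATTGCGCGCGC
>V09
TTACATTGCAAGTGCAGCTAAGAGAGTCCGGCCCGTCACTTGTAAAGCCATCCCAAACGTTAAGTCTAACATGCACAGCA
TCCGGCTTCAGTCTGTCCTTCAACGACGTCAGCTGGGTACGCCAGGCGCCGGGTAAAGCTCTTGAATGGGGGATTAACCG
CTGGTGGTCTACTGGATATTGGGCCAATCGATTTACAATATCACGTGACAATTCTAAGAATACGCTTTATCTTCAGATGA
ATTCGTTGAGGGCTGAGGACACCGGCGTTGCGACTTATTATTGCGCGAAA
>V10
TGCATGGCCGCAAGTACAGCTTCGTGAATCAGGTCCCTCGCTGGTTAAACCTAGCCAAACGTTATCACTCACGTGTACCG
CTTCTGGGTTCTCGTTATCAAACCGCCACGTCAGTTGGGTCAGACAGGCCCCGGGGAAGGCGTTAGAGTGGGGCATTTGG
GCAAGGAAGTGGACGAATTACGGTGCCAGACGATTTACCATTTCTCGAGATAATTCTAAAAATACGCTCTATCTTCAAAT
GAACAGTTTGAGAGCCGAAGACACTGGAGTCGCCACATACTATTGTGCGAAA
>V11
GGCCATGGTACAAGTACAGCTCCGTGAATCGGGGCCATCGCTTGTGAAGCCGTCACAAACACTATCACTTACATGCACAG
CGAGTGGGTTTAGCTTATCATACTTCGATGTGAATTGGGTGCGCCAAGCGCCCGGCAAAGCGCTGGAGTGGGGTATTGGC
AATTGGGGTACCACAGCTTACAAAGCGAATCGTTTTACGATTTCTAGGGATAACAGTAAGAATACCCTATACCTGCAAAT
GAACTCCCTCCGGGCGGAGGACACTGGCGTTGCGACATATTACTGTGCTCGT
>V12
TGCGACTGTAACACAAGTACAGTTGCGTGAGTCCGGTCCATCGCTCGTAAAACCCTCGCAAACCCTTAGTTTGACTTGTA
CAGCATCCGGCTTTTCATTATCAAATGGTCGTGTCAGCTGGGTCCGCCAAGCACCGGGTAAAGCACTGGAATGGGGAATC
GACAATACCAACAATACCAGTTATAAGGCTTCTAGGTTTACCATTTCCCGAGACAATTCAAAGAACACTCTTTACCTGCA
AATGAATTCGCTTAGGGCGGAAGATACTGGGGTAGCAACCTATTATTGTGCCAAG
>V13
TCTTTTAGGACTCCAGGTGCAACTTCGTGAGTCGGGTCCTAGCTTAGTAAAACCTTCCCAAACGCTGTCACTAACTTGCA
CGGCAAGCGGATTCTCACTCAGCTTCCATAATGTTCGTTGGGTGCGACAAGCCCCTGGCAAGGCGCTGGAGTGGGGAATA
GGTAACGGAAACGACACGGCGTATTCGGCTGATAGATTTACGATAAGTCGAGACAACTCAAAGAATACGTTATACCTTCA
GATGAATTCGCTTAGGGCCGAAGATACCGGAGTTGCTACGTACTACTGCGCAACG
>V14
CTGTACTTTCCTGCTGGCAGGTGCAGCTCCGGGAATCAGGGCCATCTCTGGTCAAACCAAGCCAAACACTTTCGCTGACG
TGCACTGCTTCAGGTTTCTCGCTTTCTTACACAACAGTGACCTGGGTGAGGCAGGCTCCTGGTAAAGCCTTAGAATGGGG
TATAAGAAAAACGTCCTCCACGAATTACTGGGCGGGTCGCTTTACGATCTCCAGAGATAACTCAAAAAACACTTTATATC
TTCAGATGAACAGCTTACGGGCCGAGGATACCGGGGTCGCGACGTACTATTGTGCTAAA
>V15
TTGCTTGCAAGTACAATTGCGCGAGTCAGGGCCATCGCTAGTAAAACCGTCGCAGACCCTATCATTAACTTGCACCGCGT
CTGGGTTCTCCCTCTCAGCATTCGGCGTCCGATGGGTCCGTCAAGCTCCGGGAAAGGCTCTTGAATGGGGGATTACCGGA
GCAAAGTATACCAAGTACGCTGCTCGGAGGTTCACCATATCACGAGATAACTCCAAAAACACTCTTTACCTGCAGATGAA
CTCCCTACGAGCTGAGGACACGGGCGTCGCGACTTATTATTGTGCAACA
>D01
AGTTCTGGTGACTATATTGTCGAT
>D02
GTGGGTGGTGTAGCAGCTCACGGTCATGCCAACATCGCGTAT
>D03
GCTTTGCAACATAGA
>D04
GATAGTTTCCCCTACTTA
>D05
ATCGCCGCCGGGGAG
>D06
GGGTCGCACGAG
>D07
GTCAACTACGTAGGCGCTCGGATGGGCGCTAAGGGA
>D08
GCAGGGTACGGCGAATATGCGGAC
>D09
GTGGGATACCACGTTTCATACGATGGTGGCTATTAT
>D10
CGAGTCGCTTATTACAATATCGGGCCTTAC
>J1
GACGCTTGGGGTCAGGGGACAACGGTAACAGTAAGTTCA
>J2
GACGCATGGGGCCAAGGCACTACAGTTACAGTCTCATCA
>J3
GATGCGTGGGGGCCAGGGACTACTGTAACCGTCAGTTCG
>J4
GACGCGTGGGGGACCGGAACCACCGTCACCGTATCGTCG
>J5
GACAGCTGGGGCCAAGGTACTACTGTTACTGTCAGCTCC
>J6
GAAGCATGGGGGCAGGGCACTACTGTTACGGTAAGCTCT
>C1
GCCTCAACCACGGCTCCGAAGGTGTATCCGCTGGCT
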