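>IGHV1-2*01
TTCGTAATCGTGACCGGAGAGTATGGGTCCCTCGCCATGAGTGTAGGCGCGATCACCAAGTGACATCTCAAACCGACCATAATTCTCGATATGCGGACCGTCAGATCCCATGATGGACTGTGCGTGGATCTAGGCACCGCTAGTCGTAAGAGGTATCTTAGGTGCGGCCGGGGCGGGGAGCTGCGTGTCCGTTCTTGAATTAGCGGGATTGCCATTCGGCTGACACTACGACGTTCGTAAATCTCGGTGATGCCGGTGACGAATCCGGAACCTGCCTTGTGTCAACAC
>IGHV1-69*01
GGAACGCGCACTCCTCTTCGGACTTCGCGAGCGGTACGAGCGTCGCTATCGAACAGACCTGTGGAAGGACAAGAGGCGAGCTGGAGATTCGCTTATCTAGTATGCGGACTGGGCCTCTGGAGCACTGCTCATTGGGCAACATTTAGCATCGTCCGGTATACTTCCGCGCAAGTTGTATATTATAAGCCTGTTGTGTGTCATTCCCCGTTAAGTTACATATGTTTCTTGACCTCACCCCGACCACAACTTGATAGCGTTAACACCTTGAATTGAAGCTGATGTGCTAAC
>IGHV3-23*01
AAGCAAGACAGGTCTTTCCAGATCAGAGCACAAACTTAATTCGAGTTCATCTGATTAGAGCGTCGACTGCGGGACTGGTAGGTTCATGGTATGCAAGAAACGGACCGTATGACGTTCTATGTCGGTGCAAGCCGCTCAAATGAGGGAACAAAACATTGTGATATCGGGAAAGTAAACCGTTCTTCTCTAGGCATAGAGCTTACGCGGTTCGCGGGAAGAGATTGACTGGATCCCACCCTAACGGGGTCAAAGGCACGGTAGACATTTACCCTCGGTCTCTGTCGGTCT
>IGHV3-30*01
GAGTTTTTATTGAGCTCAGCCCCAAGCTCAAGTTATTTCTGACCGGGACGATCCACTGACCGCCGACCCCTAATACCTATATGGACGGCGCCCGATATGACGTTAGTGTTAGCTCGGGAGTTAAACGCTTTCTGAGGGTGAGGAGCGGGCAGGGTCAAGCATCTCAAAGCTCAGGGAACAAATATAAGATTTCCGACTGGCCAACCTTTCACTCCGCGAAGGTCAAAAGTAATCGTGCCTTCTCATCCGATCTCATGATACCTCCTAGCTGGCTTAAGGTGTTTAGTG
>IGHV3-33*01
TCCTTTGAAGAAAATGGCATCTAGGCTCGTCCTATGCCTCGTGTCGGCTTTCCTTGGATCTGGACTGGAACCATCGACGTATCTCTAAGTCTGCCCTTCGCTCTCCACTCTCCATGCGGGCCCACTGAGGTCGTAGCGGAAAACCCTCACTAGAGTCCCCAAGCTGATGATGGACTTCCCCCAACCGGCAAAGAGGTAAATCGTCGTTACTTGTCAGCAATTTCTAAATCTGAGATATGAGTGCGGTAGTCTCGCGCTCTAGCTGATAGGCAGTACCGCTGTATTTTC
>IGHV4-39*01
TCAGCAGACTCCGAGATGGGTCTTCCGCAGGACGCAGGCGTTGAGCGATGATTTCGTAAGTACTGGGCAACACGCGCACTGGTCAGTCGCAGCTGTCGTCAAGGTGACTTTCAATACTACTCCCAGGTCTGCAGCGCTCCGACGTGTCTTAACTATACTTAACCCCATGCAGCTGCCCGAGGGGGTTAACTGTGGTGATCGTATTCGCAAAGCATCTTCCTACCGCAAATATTGGCGTACTTTCATCCATGAAGATGGGCACCCTCATGACGTGCTAGCTGTACCCGC
>IGHV4-59*01
TGTTTAGATATACATTGTGAAACTTGACTCAAGGTATATGGTGTGGATCCGGACGCCGGGTGTTTTTGGCACTGCTTCCGGTGGTCGCAACTGCAGCAGGGAACCAGTTCCGCTTCAATAGTGATCCCTGCACGAAGAAGACGTATACGTTAAGTGACCCTCCCCTGGCGTACGTAGGTGAATCGAGTTGACCAGGTTCCGCTACGATATAGGTAGCGTTATATAGCGGAAAAGGGGATTTCAGCATATTTGCACCCCGGTAGAGCATAGAGCACTAGATGTCTCATG
>IGHV5-51*01
GATTTCTTTCAAAAAAGTCAAACCAGTACTTTGTCTCTCATTAGAAGCCCAGGGTCCCTCATCCTCTGCACGAAAAATCGAGGGATACCTGACATCGAGCGCCTCCAGAGTAAATAAGATGATCAGTCCACATTTTTTCCCCATATAGAACGCCAGTGTAATCGCGACATGATATCTATGTCACAACCATTATCCTTCATGTCAGTCTCGTGAACGCACAGCTAGTGAATCATCGCTTGACGCCTGGAGTCGGCAGTCTAGCGGTTATCAGTTAAGCTCTGTGAGGCC
>IGHD2-2*01
CTCAAGAGCTGAGACA
>IGHD3-10*01
AAAGCGTAGACCAGTT
>IGHD4-17*01
TGGGATTCAAACCAAA
>IGHD6-19*01
CATCTTAGGGATTCGC
>IGHJ1*01
TCCTTCCGATGGAAAGATCTTACAGCGCCATTGCTATCTTCGGTGGAC
>IGHJ2*01
TATGCTGCTTGGGTGCGGGGCAATGTTATTGATTAGATTTCCTTGCCT
>IGHJ3*01
GACATATGATGGGCATTGTAGAATCAGAAAATATAGCTGCCGATATAA
>IGHJ4*01
AGTCTTGAGTGGAAAAACGGCACTGAGTCAAGACTAGATGCCCGCCAG
>IGHJ5*01
CGGACGACGTGGAACTCCCCTTCCGGTACCTGTTCCGGGCGGTCGTGA
>IGHJ6*01
TTGATATTTTGGTGCACCTCTAGCATTCAGACAAGGCGCCCCTGATGT
>IGHM
ATACGTATCTGAACCGGTAAGGGTGTCAGTGTGGGCGGTA
>IGHG1
GAAGTGGCAAAAAAAAGCGCAAGCTCATCGAAGGGTTCTG
>IGHG2
AGGAGTTAACAGAGGGCTACTTCGGAGAGTATCCGGTCCA
>IGHG3
ATCCCTTGTGTGGGGGTCCGCCAGTCCGCACAAACTCTCA
>IGHG4
CCGCCTATCGTCCTAATGCAATAGGCGTCAGCGACAGATG
>IGHA1
CGACCCTTGAATACGATTATACTGTTCGACAGACGCGACA
>IGHA2
CAGCTAAGATGGTCTCGCTTTAAGAGCGCCTAAATATGCG
>LEADER
ATGACGAAAATTAACCAT
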