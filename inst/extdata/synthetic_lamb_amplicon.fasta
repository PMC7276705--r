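>synthetic_lamb_amplicon cds=101-1441
CTTATATATTTATATTCAGCGTGGCAATCTTTCCAAGGCGTTCGGTAGACGGCTTTGGAAGTCTCTCAGGTCCCGTGATC
TGATCGCCGTTCAAGCTAAGATGAACAGAGAGTTCGGTACCCGGATTGTTAGTTTAGGTGTTCTTTCGGCCGCGTATCCG
CTGGGTTCCAAGCCAGACAATTATCGGACCCAGGACTCTTTCGCATCGTGGCCCTATGTGGGGTCTGTCTGGTCTTACGT
GGCCGACGACCGGCTAGCACCGCAGGCTACTGTAAACACCTCCTACTCCGCGCGTTTCGAATTTGGCATACATGGAACTA
AAAAATTTATCCGACGAACACTCACAATCCGAGGGCAGACTCAAGTACCCGCTGGAAAGGGCCCAGTGGGAGTCGCACCG
AATCGGACACCTAGAGCCAACTCGACGTTTCGATGGATAATCTCAGAAGCGACTGGGCTGTCCCGCGCTAAGATCCGGTT
ATGTTCAGCCTCAGATCCTAGCAATCCAGGCGGATGTGGAACTAACCGATTACTAAAGTTAAAGACGAATTTTTCCTCGC
ACCAGGTGTCTCATCCGCCGTTTTCTGGGTCGGTGGATACCCTAAGCCATACCTTGCAAGGGCCGTACCAACCCTATCGT
TGTGTAAAGATAACAGGTACCCTTGCCCCCAGCGGGTGTCGTGGGCTTACGCGATGCAGTACTACCGGCTACAGTCTTTT
TTGCCGCTCTAACAGATATCGGCCGCCCACCCCTCATTTTGGGCGTCCTACGCGACAAAAAAGCACGGTTCCGGAGGGTA
CGCGAAGGTCGTGGTGGCATCCGGCGCCCGAGCAGCTGGAAGGGAAGAACGCTTACGCCAAACCGGCCACATCGCCGCGT
GCTGCCATCTCCACTGCACGAAGCTATACGCACATACACAGCCGCACCGACCAGCACTATTCATGCACCGTCAGGTGTGA
GCTCCGTACGGTAAGTGGAGTTTCTGAAGTACAAAGTCCAGAGGTTGGATGCGACACTACAGAGCTTTGTGCTATACGAT
ATCCCTCTGCCGTGCACTGCAACGATAACGCAACGGCGCGTCGATATAAGACCATAGTTGTAGAGATTTTAAAGAATTAT
TCTGTCAAATCGGTGTCGAGACTTACACGACCGCCCTTCCGTGCAGGAGAGACGAGTATACGGCTACATGGTAATGATTG
TATTTTCGTGTTAGATGTCTTTCAGAGGAACTATGAAACTTGTCTTGAGAGAGCAGCGTTGCCCGTTCCTGCGCGCACAG
CCGGACGTTGCGGCAGGCCTAAAAACCATAGTTCCGAGCCGTTCTCAAAAACATTCGGGAGGTCTCCTAAATGTAGATCT
GCACGTTACTCTCAGAATGTTGGGTGCTCACCGCCTCATGATGGACTGGAGGCCCGAATATACGTGGATGGCCCTTTTTA
AGAAAGTAGATTGTTAACTTTGAGTATTCCCGCTCTGTGGTGGGACGTTACACATCGTAAATCCCGATGCTAGGGGATCC
TACCGTGTGCGCGGGAATATG
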