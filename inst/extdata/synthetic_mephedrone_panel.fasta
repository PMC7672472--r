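>MMC1 protected_length=42 panel=synthetic
TAGAATAGGCTTTATTACAGTCTGATGAAAAAGGAGATTTTCGCCGACCCGTGTCGACTACTCAATAAAGGCC
>MMC2 protected_length=42 panel=synthetic
TGTATAATACATACCGGTATCCAATGCACAAAGTTGTTACTAATTTCGCCTCCTGGTAGATGGTCTGAGAAAC
>MMC3 protected_length=42 panel=synthetic
GTAATACCCGTGTTCGAGGGAGGTCCTTCAAAAAACACTTGAGAGTCGAAGAGCTTCCCTTACTAGTCTACGA
>MMC4 protected_length=42 panel=synthetic
ATTTAAATTATTTTCCCAAACAGATAATCGTACAAGGAAATGAGCCTGGGAGTGCAGTACTCTTCCTGAGAGG
>MMC5 protected_length=42 panel=synthetic
CATCCCGAATAGTCTGCGTTATCCTAAAAAGGAAAGGCAGGAGACCTCACGACGAAACAAGTCCTCAGGAGCC
>MMC6 protected_length=42 panel=synthetic
GTCCCGAAGCCGTCGTATGGTTTGTTTGGGCGGGAAAAAACAGAGTCGTCACCTATTTTACACGAGGAAACCT
>MMC7 protected_length=42 panel=synthetic
ACAGGGTAGGACCTTCTGGTAATACCCTAGGATCGGACGAGGCTGCCCCCCAGCGTCATAGCGGCGGAGATAA
>MMC8 protected_length=42 panel=synthetic
GAGAGTATGAAAAGGAATAGAACTCGTAGCGGTTCGCTATTACAGGCCATGGAGAGTCATTTCACGCTAAACA
>MMC9 protected_length=42 panel=synthetic
CAAAGAAACAACCAGTCAGGCTACGAGGTGGGCGATCTGCAAGTATTATTTCGTTGCCCGTGCTACCTGGGCT
>MMC10 protected_length=42 panel=synthetic
GAATGTCACAGGCTCGGATGATGGAGACTGTACAGCTGTGCCGTGCATGTGGTATCTATAGAATTTCGCGACT
>MMC11 protected_length=42 panel=synthetic
AACAAACGGCGAGAGGGGATGTTAAACATTAGGATACTTTATCTTTTCTCAGGATTAGAGTGCCATAATGTCG
>MMC12 protected_length=42 panel=synthetic
GGAGCACCGCTGCGCTCACTATTTTTACAGCCCCACTAAGTAATCCTCCTGCTTTGAAGGTCCCACGGTAAAT
>MMC13 protected_length=42 panel=synthetic
GCACAGTTAAGATAGTGGCGGCCTCAATATGCTTTCGGCTGGAGAACACGTCCCCCAGGGTATTCTCGCTGAT
>MMC14 protected_length=42 panel=synthetic
CAGACTTACGGACTGAGAGCCAGCTAAATTCAATGGGGAGGACGTGTCTCTGACATTGCATTTGTTGGGGGCT
>MMC15 protected_length=42 panel=synthetic
GGCAGGAGACAAATAACCGAACTCGGGTTAAGCACCTTCCTTCGGGAACACATGCTTGCGGTATACTCCCCAG
>MMC16 protected_length=42 panel=synthetic
GGAACGGTCAACGACCACAGTAGTCGACCGTGACTCCGTATATTACCACCGTATACTAGTAACGTTGCGAGAG
>MMC17 protected_length=42 panel=synthetic
ATGTCGGAGTTGATCTGCGGGTATCCCCGGTAGATCAGGGGCACATATCTCCAGATCAAGTCAAGTTCTTTCG
>MMC18 protected_length=42 panel=synthetic
TTTGTCACCAGGAATAACTAATTTCGATGCTCATCGCGAGTGTCTAAGGTTACCATCGAGCATTCTATTAGGT
>MMC19 protected_length=42 panel=synthetic
GCCCCTTGTACTGGTCACCCGGTGTGCCTTATAAGCTGGAACTTCATACCCGCGTGCCATACACCAACGACGC
>MMC20 protected_length=42 panel=synthetic
CAGTGGTCACTATTGATATTGGTTTGTTATCTATAGGGAATAATTACCCGACGTAGTACGAATGACAATCTAT
>MMC21 protected_length=42 panel=synthetic
GTAGGGCAATGTAGCTGACACATTACTCTCACGTGTGCCTCGTAAAACGAGGAGGTTTGGGACTGGTACTGTC
>MMC22 protected_length=42 panel=synthetic
TTACCATCACTCCTCAACCAACACTTCTTGTTAAGTAAGACTGGCGAATATAGATTCGCGCCGTACCTGAAAA
>MMC23 protected_length=42 panel=synthetic
ACTAGTTGGACGATGGACTATCGCGTGTGTTATGGTAACCACGATTATAGAACCATGACCTTTGTACACCCTG
>MMC24 protected_length=42 panel=synthetic
TAGTCCACTTCGTGGCAATCGGTGAAAGGAGCGGGCGCATATTGAAAACCCCGTGCATACGGAAATGCTCTCG
>MMC25 protected_length=42 panel=synthetic
TCGTCTCAGGCGAATTAAAGAGATACAACTTAGGGGCCCAGCGCGACTCAACCTTCAACGGCACTATAGAAAA
>MMC26 protected_length=42 panel=synthetic
CAAACAGAGGTCCACTTCCTAACACCTGGAGTATATTCGGCTCCTGGACATTAAGACCGCCTAGAATACCCTC
>MMC27 protected_length=42 panel=synthetic
ACGCAAAGCAGCTGGGTATGGCTGTGTAAGACTTTCTTTGACTTCTGCGATGGGGAACCATAATAGGCGGATT
>MMC28 protected_length=42 panel=synthetic
ACGGCGGAGGTCTGGGCTATTTGCTCTTATGCTTTGTTGGTCCGAGAGCACTGCCACTGGCATTAGCTCGATC
>MMC29 protected_length=42 panel=synthetic
AGCATAACTGACTGCGGTGCCATTGCTTTCTCGCATTATGCATTTCTCTCACCGGCGCTGGTATAGCTCATAA
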