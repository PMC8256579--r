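>gpt E. coli xanthine-guanine phosphoribosyltransferase coding sequence (456 nt, coding strand)
ATGAGCGAAAAATACATCGTCACCTGGGACATGTTGCAGATCCATGCACGTAAACTCGCA
AGCCGACTGATGCCTTCTGAACAATGGAAAGGCATTATTGCCGTAAGCCGTGGCGGTCTG
GTACCGGGTGCGTTACTGGCGCGTGAACTGGGTATTCGTCATGTCGATACCGTTTGTATT
TCCAGCTACGATCACGACAACCAGCGCGAGCTTAAAGTGCTGAAACGCGCAGAAGGCGAT
GGCGAAGGCTTCATCGTTATTGATGACCTGGTGGATACCGGTGGTACTGCGGTTGCGATT
CGTGAAATGTATCCAAAAGCGCACTTTGTCACCATCTTCGCAAAACCGGCTGGTCGTCCG
CTGGTTGATGACTATGTTGTTGATATCCCGCAAGATACCTGGATTGAACAGCCGTGGGAT
ATGGGCGTCGTATTCGTCCCGCCAATCTCCGGTCGC
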