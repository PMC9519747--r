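>synthetic_island1
GGTGCCAACGAGAGTCTTAATTGCTTTACTGGCAACCACAGTCCTTTAGCGGACTCGTCACAACGTCCGGGAGCTAGCGTCGACTTCCTAGGGGACTAATTAGAGAACCTATGGGAACCGTTATTGAATTTCTAATTTGTCCAGAACAGAGAGATGCCTGGAGATCACATCCCCTAGTACGTGCAGATATCAAGGCCGACGGCAGGGATAGAAATAAAGAGTCTAAGTACGTCTTCCCAGTGATCATCATTTATGCTCTACGTGGGCAGAGTGCCATATGTACTGTCTGTGCGTACTTAC
>synthetic_island2
CGCACTTACCTCCAGCGCTCTACCCAAGGATCTTTGTCTATTGGTGTCCAAAGAACTTAGTGGCGGCGGCCCTAGTCTCAGTACGTCTCGGGCCGCACAAGGAGCCTAACAACCTCCGCAGAGAATTATCCTGCGCAGTCCACAGACTAGTACGGTCTGCGGCTAGTTATCCTCCGAGGGAGCACTGGAGCTGGGTGACCTTCTTACGGCTACTCACCATGTACTAACCAATCTCTGGGAAACAACAGCGAGCCCCAATACGTCGACTACTGATACCTCGTCTCTTGCCCTTTGTCAGCT
>synthetic_island3
TAAGCTGGATACCGACCTTGTCCGGCTGTACCTCGCACCCCCGGTAAGCCGGACGTGATTCGGGTCTGACGACAAGGCGAGGACCCGTCAAGGTAAGGGCCCCTTTGCGTTCCTAGGGGACTAATTAGAATATGGCGTCGACGCGGCACGGGAATCGCTGCAACTGTTGGCCCGGATGCCTGGTTGTGGCAGTTGCGGAGCCACCCGTCTAGCAAATGAGGAGCGTTAGATATGGGCCAAGGCAGTGCACATCGCGGACGCGGCATTCTAGAACTACGTAACCTGGGTTTAATGCGGTTC
>synthetic_island4
GGCCAGAGGTCTAGCAACGTTCGGGTGCTCCCTTCTATACGTCTAGGTAGCTGAAAAAAACATAGAAATGTCGTTATATCTGAGTCCGCGACGTCAGGAGTTATGCGAGCAATAGCAGATGCTGTCGGGCGTCTTCCCTATGGGACTAATTAGAGCACCTGGGCGCCAGCTTCCCGGGAGATCCAGTTGTGCACGTTATAGGAACAATACCTGGATTCAACGAGGAGGGCCCGGCTGGGCTAGAAACAAAAAGACTCGGAACTGTAGCGTTAGCTATTTGGTAATTTGCCTATCTATATC
>synthetic_island5
CCACCGACTGGTAATTGCCTAATCTGTGCCAAATGTGGATGCTACCCTACAGAGAGCTGTCTCAGCATATCATTCCCGTGAGCTTGGAGATGCTGACTCCCTATCCCTGGAAGCCAAAAGAAAGCAATGATAATTGGTGCCAATTACCACTGCCGAGTATGTAGTTTAGTTGAACTCGATGCCGTAAAGCCACGCGCAACGATGGCAAGTAATCTTAGCTGTTGGTACTCCGTGACCTACAGAGCACTTCGCGCTGCGCAGTTAAACCCGTGTCAGCACACCTAAGCGTGTGGGGGAGCA
>synthetic_island6
TTGGACTTGCGCGGGGCTTTGCGGAGGCGGGTGCAGGGGATAGGGCTTAGTGCGTGGGGGGCAGCCGATTTGTCCTATACAGTATGATGAGATGACACCTGCAATACATGTCATGTCGTCCTACAGAGCCTGTTCCGAGGTCGTATATCATGGCACGTATTCCTAGGGGACTAATTACAAGTACTAGCTTCCTATTGCTGGCTTATACTGCTTAAATCGCGGGTCTAATACCAATCCCCGGAGGAACCGGTTACGTTAGGAACGAGGGCTTCATAGAGCGAAAAGTACATGTGGAGAACC
>synthetic_island7
CCTCCACACCCAAGCACTAGCGTTTCGTTTTTGACATCAAACTTGTAAGGACAGGTGGAACCTATTTGGACAACGCATGAGCGAAACTCCATAATCCCCAACCTGAGCTAAAAGAAAGTATATTCTCCCGGCGGGCTAACTAGATTCTGGGATGGTTTGGGGGACCCTCCGTGTCTACTCAATAATACTGGAAATGCCCCAAAGCCCCCAACGTGGATGTTCCCTAGCCGGCTCTTGACAAGGGTCATCCCTCTTAGAATTTAGCTCGTTTGCGCTTGATCGAAATTTTATCCAATTTCC
>synthetic_island8
AGCTGTCTTAAGCTGTTCCGTCGAATACCCTGTATTCCAACTGCGAGCGTCAAACTACCCAATCGCTCGCCGAATGTTGCCCCCGAGACTACTTGTGATGTAAGGCCCTGGTCTCGATGACCACACCCGCAATCTCAATTGGTTACCCGGATCGGAGATTATTGGCAAAGGAGGTGGAGCTGCCTTCCCAGGGGGCTCATTAAAGTATCATTTTTTAAGAGGGCAAAATATAAGTCAGATTTCACGTATTACGGCAACTTATTGCCACACTGCGTTGCCAATGTCCCTCTCTGCGTTTTG
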