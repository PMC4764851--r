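>LINE-consensus-1 synthetic LINE consensus
TTCTAAACTAACGGTGTCGCGCGAGCCATGCGACCGCTTGCCAGGTGCTTCTGTGATATGTAAACTAGCTCAAATGGTGGTGTGATATGAAGTCAAGCTTGAGTCTTAGAGCAAGGAAGTGTCTTAACAGTGCTCTGAGACGCGTGTGTGATTACATCATACTAGCGCGGGTTGTAAATGTTGACCGGCCCTCAGAGGAGTAGGGCTCCCAGGACAGCTCAGCGGCAATGGGGACGCTCCTGGAACTCACAGCTCGTCGAATAACAGTAGCAATACTTTCATCGAGTTGTGCAGTGAGAGGGATGTTAGGAATGGGTTGTGATTATCTCGATTTCGGCCGCCGAGTGCCAGGGCCAATACTAAAACCGGATTAGGAAAGTTAGGTCAATGCCATTGTTTCCTTGGTTGTGCGACCACCTTGGATACACCCTCAGACCCGTCTCTTGTCGCCAAATTCGACCTATACGAGCGTCTGGGCTGTAGCGCCTTAGACGAAGATAACAAGAGAGACAGTACAGTCGGGCAGGTATAAAAAGTGAGCCGCTCCTAAGGGGCCTAGGCTAATATTCTGTTTAGGGTACAATTGTGACTGATTGATAC
>LINE-consensus-2 synthetic LINE consensus
AGGTCATCGGTCCATCGGCTGCTTAATGGCTAAAGAGCCTCAGCCGAGTGCTCTTCAAAATAATGGTCGCAATAGAAGGAATAGTGAAAGTTATCCCTGGCCTTTTGGACGCGAAAAACACGTGGCGACGGGCCGCCCGATCGCAGCCCGGGGGGGGACGAAAACCTGGAGCGGTCTGTGGCGAGCGTCTCTTCTTCTTGGACTGGAACTACAAGGGCTAACGATCCCCACCACAGGGACAGGTCGCCAAGTTTAGGCGGCCACTTCCATCGATCTACTCGATGCTCTATTAGTACGTTCGTTTGGCCAGGAGCAACGGCAAATAGCCTCGCACGGCTACCCGAATACATGCTCCCTCTTAATCTACGACAGGGAGTCGCCAGACTAAAGTCACATTGTCCTAGAACTAGGAACATACTACATACGCCTTTGTGTGTTCCGCGTAGAGAACGCACACGTCGTTTGTGGAGGGACGCAGCTACAGATGGCCCGGTAATTCG
>SINE-consensus-1 synthetic SINE consensus
CGCCGCTCTGAGAGAAACCACAAGTTTCTGCCAACGTATTCCAGCCGCCGAGTGTTGTCCATGACAGCCATTTGGCCGATGGCCGGTATCTGTTTAGATAGTGGCTAAGCTGGTCCCCTGATTGCAAAGCTGGGGAAGGGCAATGCCTTGTCTTCTCGGAATAAAGCAAAGACACCTATT
>SINE-consensus-2 synthetic SINE consensus
AGGTGAGAGTCATAAGTTTTTGTCTCTGCAGTGATCCTGGTGTTCGATGATTGCCGCACCTTCAAGCGACGGTGTCTCGAGTCCTCTTCCCGGGCGTCACGAGGAGTGTGATGCGGTTCGTAGTTTATCATCGTCGTGGTGCTTGAGCTT
>LTR-consensus-1 synthetic LTR consensus
AGTTATCATCAGGGATCCGAGGCTCGTACTGGACGTAAAAGCATCCTCCCTATAGGTCGGTGTGGGGGGTCCTTGCTAGACTCGAAGACTAGCTCTCTGTAATGCCCGACCAACAGTGGGAGGACATCATGAAGGTAACGACGCCATCCTGGAGCCACACGCCGCCGAACACTAACACACTCATAGCGGTTCGGCAAGTGGTAATATCCCTCGACCGAAGGCTTACCTTGCAGCCCTAGCCCAGTGAGATTTTATGCCGAAGTATCGTACAGGCCTACCAGTGAAAGTTGTCTCTAAGCTGGAGAGAAAGGTCTTAACTTCATTCTCATGCTCAGGCTGTGATTTTTTTACGCTGACTAGGCTAACCCCACAAAACAAGGGCAAGGTGCACATGTATCCAACCGGGCAGTATTAGAGAGGGGGCGCGCGTAAGTTGCGGACACGAGTTAG
>LTR-consensus-2 synthetic LTR consensus
TACCTGCTAATGTGGGGTCTCTAAACGAAAGTCAGAGACACATGAGGCCAAGACCTTCATGTGCGCGCAGCGTATTACCAGTCTTTATTTCTAACACCCCCTCTTTCTAAGGAATGATAACTGAAGGTCCTGATATCGTAAAGAACGTTGACGGGAATCAACACGTCGCCGGCCCATTTACCAAGATCCTCTTTTCCGACAGGGACGCAGTTTACCAACTCACAAGTTTCAAAGTCTTAGGCACCGCGAAGAGGTAGAGTTTTTACATCACGCGACGAAGAAAAACGGAATGATCAGAATACCCGCAGAGACCTGATTACGCTAATTTAATATAGACTGAAGATATTTCGTGAGCGTACATGTGGGTTCGTACCTAATAACGAGGTAGATTGACCACCTC
>DNA-consensus-1 synthetic DNA consensus
CTCGCAATGTCAACAACATTTGCAAGCCTTACGAAGCGGTGGTCCTAGAACCATGCCTTGCGCAGTTTTGCGCATGAGGTTCCAGCCTTACGAGCCGGCCTGGTCTTCCGACGGTTCAGCTGGGTGACAAGCTAGGAGTATTTCCGGGCAGTCAACTAGCAGCGCACTTTGATCCCCTGTAATTATTGAAACTCGTCCAAAAAATATAGTAAATTTGGGGCTTTCTCAATAGGCGGCGGGTATAGAGCACGCATCATGCCCAGGACACTACTTCTTGCCGGAGTTTATTCAATCATTGGGTACCATGATATGGACTGGGCACTTATCGCATCTAAAAAAACGTTGAACGG
>DNA-consensus-2 synthetic DNA consensus
GAAACCTACACCGCATCCTACGCGGGGAGAACGCGATATAGTCCTATCTACATGGTCGCCTCAGAGTGCACGACGGCCTTCGGTCTATAAGAGATCGATCGTCCCGTTCGGGCGGCGATTACGTGTTAAGGCGCTTACGTGTCTCGTGTTGAATCTAATAGCCGTTGCATCGCGGAAAACCACGCAAGCCAACCGCGTGATGGACTTTAAGCTTTTCTGGTTGTCCTATGGACAAGCCGGGACCATAAAAACACCGGTAGTACAGTAATACTTGAACGGGTCCAGGGTCCTTGCCCACCT
>Retroelement-consensus-1 synthetic Retroelement consensus
GAAATATAATAAACGTGGGATTTCTAACATGCCACGGGCCCGTGCACCGTGTTCATCGCGCATGACGACAATCAGAATGTCATTCATACAGCAGCGGCGGGAGGCGAATTGGCGAAGTTACGGGCATTTCAGTGAACGGACCTGTGCGAGATATCCAGGTACGGTAAACCTACTTCCTGCGCGACACATAAAGCATAGCCTCGGACTACAGCCGACTGAAGATTATTGTACTTGTCTGATAAGTTGAGGTCCATTCACTTCAGCCGGCCGTTTCCATACTTGAAAGGGAACTATGCCATTTGTAGGCGGCAGATACCTTCCCTTTGACAGGTATTCGAGTTAGGGGTGTCAATTACCCGAGGAATGGTGGGTGAGAGCCGAGATTCTGCCTGGAACGATGGACTTACAGCTGTAGGTGAC
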