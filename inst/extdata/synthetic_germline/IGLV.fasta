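>IGLV1-S
TTGTCCATCTTCGTCATCCTTTTGCCTAAACAAGGTGTTGTGTACTATGCAGAGATTAACCTGTGTAAACGTATTGAGCC
TAATCCCTGGGCGATCCCAATGATACCCAAATTTAATCACTCCAGGCAATGGTGGAGAGATAACCAGGTTACACGGTGGA
GAATGATGGAAGGAATGGATCAGCCTTTCACCTTATTTGAACATGCACCTCGTCACCGACAACATAGTTCAGTAAAGCGA
ATGTCCCGTGACATGGTCTCCAAGAATCCGATTCACTTATGTAATGAT
>IGLV2-S
CAACATTGGTGGATGAAGGAACCCATGTACGAAGCGCGTTTTCCGCACTTTAGAGTATACAAATGCGATATCAAAACCTG
GGGGAAGATGAACGCTCATCAAGCAAAAAGCAGCAATCATCAAAAAATCAAAGACCGCGTCCCAATCCAAGATATGATGC
ACTTTGATGATGTGAGCAGTAATGACGAATGGAACCCGTCTCCCCCAATTGCCTCCTCTCTACCAGACAGGGGATATCCC
GAAGGCATAATGATGAACTATACCTTAGTACGGACGATCTGTCAACCC
>IGLV3-S
ATTATGCTTGGCGGGCAACGTACTAAGGGGCCCATCAAGCCAGTCACCTATGATATGTGGCCCTGCTATTGGCACGATTT
TGGCGGCAAGCGCGTCGAAGGCCTAGGAGTGTCTTACCTCAAAGGTTGGGCTGAGGCTTACCCTCATCAGGAATACCAAC
GTTTGGAGATGTATAGGCGCGAGACAAACATATCTCTTTTGGACACCGATGAGCAGCCTGACGACCACGTTGATGTCATT
TACCATCACTCTTTTCAGCTTATGAAGTGGATGATGTACTGTGATATC
>IGLV4-S
CGACACGTTATTCTCGTCCCTTTTCTAACGCGGACGCCGTTCAGTGGGAGCGCTAAAAATGAGTGTCAATCCAAAGAGCG
ACGCGAAAGACAAACGTTCACTAATAGCGTGAGGGTGCGTGAAATCATGGAGAAATTTGACTTTGTGATAGCGCAAGTAG
ACGAGAAAACTACTTACCCAACGATGTATACGCATGGAGAACATATGGCAAAATGGATCAATAAGTGGAACAGTCAGATG
TTGTTGCAAGACCGGAATAACGATGATCAATCATGGTACTGTCCCCAG
>IGLV5-S
ATTTTACGTGCAGAAAACAGCCCTGCGAACTCTAATTTGTCAACGAACCCTTTTCCTGAATATTGTAACGTTCGACACAC
AAAATGGGTCATAGTTATGACTTGGGAGCAGGTACATCAGCAAGGGAAGTTCGGATTAATGGCCGAAGCGCCCAGTCAAA
TGACGAGCCTGCCAGCGATGAGACCAAAGATGTGGGATCGATCTTGGAACTGGATCCCGGACGGATGGAAATACCAACGG
CCCAACACCTTTAAGTCCGAATTTTTCGACATGGCACCATGTCTCCGG
>IGLV6-S
GTCCACGAATTCGTTATTAAAGCACAGTCGCAGAGAACATTTGTATCCTGGTCAGAAAACGTTTGCGAACCCCCTGGTTA
TTGGATGGTTGGCCTAGGCAGTCAACGACGACCAACGACAAACCTAGCCGGAGGGAAAATCTGGGCACAGAGTACTCTAG
CCGTGCTCGAGTTTAGGGCACACCCCAATTACGGAATACCAGGGGACATGTATTTTGTCGCGGAACGCATTGCGCCTTAC
ATGAGTATACGCGCCTGGGAACCTTGGTGGACATTAGGTTGTATATCT
>IGLV7-S
ATAAAGACTGTCCGTACCAGTGGTGGTAAGTTTGATTATTTCTCGACCTACCTACAAGCCGATTGCAAACATGATCACCA
AATTCGTATCGGCTCGTTCATGCTCAAGGTAGCCTACTTGTTTTGGCGCAAATCTGACTACATGGGAGTAGATGAACCAG
TCCCTGACGGACGGTCCCCAGCTTTGCATTTTGCTCTCGCCCGGGGTTCTTATTCTTTATGGGGACACTATGTCGATGCC
CAGCGCATGATTTGGTTTATGCGTCTCGACGGGCACTCGTGTGGGTCA
>IGLV8-S
CCAGTCCACCAAGTTAATCAGTTTTCGATGTTGCAGTTACTTTGGCCGTGGTACACGGGCAGATGTACCGCTCACGCTGT
CAACCAATTCGACGTTGATACATCTTACGAGCAGACGTCCTTCAGCCTTACGGAGTGGGGACAAGTTATGGACCTTCCTT
CAACGCAAGCAACAACGCGTCGCATGCGTGTAAATGCACAGGCCCTGACTTTTCATATAGGTGACCATCTGATTCACTGG
GCTCACCAGGTTGGCTATGAGATGCGACAACCGCACAACTGTTGGGAG
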