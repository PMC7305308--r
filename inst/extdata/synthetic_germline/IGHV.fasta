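>IGHV1-S
TTAAGGGTAGAGGAGCTTGAAGAGGATGTTAGACCTGCGCAGCATACGATGAATAGGAAAAAATGTATAATGATGCTAGG
GGTGCCAGAACTCGAAATGGATGCTCAGACGCGTCCTTGGAGTTGGGTACCTGACTTGATGGGTCGGGACTGGAGTGGCG
AAAATCTCATGATCGTGAAGATGTTTTTCTATCTACCCCAATGGATTGGAAAACATTATCGAACTTTCCCCGAACCGCCC
TCAGGGAACTCGTGGTTTTTGCAGAACGAAATAAGTTATTGTTGGCAT
>IGHV2-S
GCACCTAGTGGGGCCGCGATGCCCCATTTGGACACGGTAGATAAGCCAATACACGGGCTAACCTGCGGACGCAAAAAGCC
GTGGCGTGTTGCAAATTTCTTTATTGAAAACGCCTCCTCCCGGCTCCATATGCAACGCTTGAATTATCGAAAAAGCCAAA
GTAAACTAATTCGCTTTGAACTGTTCGAAGCTTCGTACTACCCTTATTTTTGGATTTTAGACAAATCCCGCAAAAAGCAT
ACTCTAATGCTTTTTTTGATCGCGATAACTAACAGTTGGTGCATGATG
>IGHV3-S
GTTATGTCGCCTGGCCCAATACCTGTACAAAAATCGATGCTCTATTGGCATAAACCTACCCAGTGCGCAGCCACTGCCCC
GGTCATTGAAGCCAACCCCCCCAACTCCGCGGATAATATGAAGGAATATATTGTTGTAGGTCAATACGTACAGATACATT
TGCCGTACTACTTTCACAGACACCACGACAATAGGTATCGCATCGAGGCTCGCTATATGAGCGCTTACGCTTGGTTTTTC
ACATTGTCAATATTCGAATCCAATAGCGACCACACCCCATGTATTCAA
>IGHV4-S
CACATCCCGCAGAATCCGAGTCCAATGCCCTCCCCAGGGCTCAAAATCATTTACAAAGCCGCGTGCTACTTTAAACAGCG
ACCAGAGGGTGAAGTTGGTGTGTACATACCCTTACGTGTGAAACACAAAAAATACCGAACTAGTACCGAAAAGACCCAAG
ACCAGATACTAATTAATATCGTGAACGATGCTGTTAACTCGCTTACCACTGATACCAACCTTGGGAGCATGGGCGCAACA
GATTCCCCAATTTACCACCCAGCTTATCGATACTTTGAATGCAAAGAC
>IGHV5-S
CACAGTCCACAGGTTGATGGGAACTCTTCAGGACCCGGTCATAGCTCAGCTTTTCACGTTATCTGCATACCGAGTACGAT
CTCGTTGCCGAACTCCCTCCATCCGAGCGTCTGGATAGAGCATCCACACGATCCTCACATGCTGAATACATACAGCCCAA
AGATCATCCATGGCACTTCGACGCGTACACCCAAGTGGGACCACGACTACGAAACTAACTACCATATGCTATTTTTAGTA
AGATGGGACGGCCCAACCCTCACAAAGAGGGGGCAATTTTGTGAGATT
>IGHV6-S
CAGGCTCCGGGCATTCAGTTCGGGGACGCGTGGCATCCCTCGTTCAGTTGGAAATGGCCCGAGTGCTGGGGTAAGTCTTT
AATGTACCCTGGGCGGCAGACAACACCGACGAATATGAACCATAACGCATACATGCAAAACACTAGGATGGCCGGGGTAT
CAATGCAAATCGACGCTAACGCAGACCTTCACGCCCGCTCAATGTATGATATGGTGGGTAAGTACTCATTGGGGTGGTCA
GTCTACCTCCTCAATTCATACGCAGTTCCTCATGATGTATGCATAATG
>IGHV7-S
CAAGGATTCCGCATAAGTCCGGACAGAAATGGCTACGTGAAAACGAGGAACGACCCGCTAGATTGCTCATTTATTTCCAT
GCGGTCTGATCTCGATGAGCGTTTTCGCTACATCGAACCTTATGAGATGTTTACGATTATGGATATCCATTTTTTTCAGC
AAAAAAACATCATCTTCGCTAGATGGTACCAAGGCGCTATGAAAAGGCCGTCTGAAATAGATAATCGTTGGTTGTTTGGG
AGTTACGATAAGTACCATGGGATGAAGCGTCTGCTGAGGTGCATTGTT
>IGHV8-S
TATCATGCTGCTATGGATGTGATACCAGCGAATATTATAATCAAAACCTATTGGGGAGCGCCATGTCCTCAAACTCTGGC
CAAGCCGACTAATTTCTCAGAGACCTTCTTGATGAAAATGAGTCAGGAGGGTCATAGTGATGTGGACAAAATGCGTGGAA
ACTCTAAGGAGATATGGCCCTTGTGGAGGAGGGCTGTTCACGTTCAGCGCGATAGGGCGTGGTGGAAGTGGCGGCAAATG
CGGGGCTCTGAAGTTACGTTGTCAATTTACGAAGAAGCGTGCTGGATC
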