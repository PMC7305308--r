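>IGKV1-S
GAGTCTGTAATGTACATGTGGGAAGATAACCAAAATAATGACGCATTAAATTATCCACTACAGTGTTTTGCACGCGCATG
GCAGCAAGCCTATGCGAGGGAGTATGACAATACTATTTGGTGGCAGATGTGGTTGCCAATGAAGTTTCACACAATGGATA
AGTTTTACTATGAACGAATGGGGACAAATAGGATTATTTTTGTGAAAAAGAGGTATTGGGCCTACATCTTCCCATTCCAA
CGCTCCCCGTTGTTCATGGAGACTAGTTGGGAAGAGCTCTGTGAGAAC
>IGKV2-S
ATGCCCCCGGATTTTGAGGAGTGGAGAGAAAAGACAGGGCGCGATCGAACTCCACCACAGCGTTGCACACAATTTACTTT
CAAGTTCTGGGTAATTTATCGTGATGAGTTTTTTCAAGAGCCGAACTTTATGATCCCAACAGGTGACGACAGACCCGTAG
GTCCCAATGGCAATGGCACCCTGTTCGCGGTTGCTGACGATCAAGACACTCCTCAAGAGCTATTGAGTTGGCTAATACAT
AGAGTTGTGCAACTTGCTCAGGGCCAAGTTTACTCGCAGTGCTTATCA
>IGKV3-S
GAGATGATTCGGATGACGCCAAAGGGGTTTTACGAAATAGGTTTTGTACCTTTTGTTCCTTGGTGTGACGGGGAACAGCC
CAGCGACCCAACGTGGATGAAAACACAGCGTGTCTTTCAAAAGATGGGAGACTACGACAGTGTCCGTCAGGCATCCGATC
ACAAAAGGCAAAAAATGCAATTATACATGAAAGGACAGGCCTTTTTATTTTATGTAGAGTTTTTGTACGGGCAACCTACA
GGAATGGCTCAGGGCCAGAACATATGGCTAGTCCAGATATGCGGAAAG
>IGKV4-S
CGCACGGTGTGGTATAATTGGCGGGAATGGATACACAAACTGTGGCGGGCATCCAATAAGAGATGTATTAATGCGATCGC
CGAATATTATTTTCTGCATATGTGGAGCGCAAAAAACATGTACATACTATCCATGGTTAGCGCACAACCAGGGTCGCCGG
CTCCCAAAGGTACCGATATAAAGCGCTTTATTGGGGGGAGCATGTGGCAAGACGAGTTCAAAAAACTTGGCGAATTGCCT
GCGGATCCAGATGATTATGTATTCCGGTTTACGTACCGATGTATTCCC
>IGKV5-S
GAGGATTTAAAGGAACGCGATGTCGACCCGGAGCATCGGCGATATTACTACACCAGATACGCGTGCATGTACGAAAGGCA
GTTACTAGATAGTCAGTCCTATGAGGAGAAAATGGCTGGTTTTAAAGCACAAGTATTCTGGTGGATACACAAGAATACTA
TGCGCATTCGCGCTGAAGAGATGGTGTGGGGGCCTATGGTCGAATATTGGTACATAACGCACGAAGTATTCTGGATAAAG
CAGAAGCAAGGCCAGAGCTTGGCATGGAGTGTGGATCTTTGTCATGAT
>IGKV6-S
GATATCACACCTATCCCCCATGAGTCCTGGCATGGTGAGTACGACCAGTACCAGATACCTGATTGTGAGAACAAGTACAA
TGGCAACCTTATTCACCGAGAGTCCAACATGCATTATCAGACGGCTAAGTTCGCGGACCACACTTCGTGGGCGCTGCCAC
GGCACCGGGATATCTGGCAGTGGCAATACTCAGCGGGAGATGGCTACACGATGGGTGAGACGGGATACAATGTAACTTTC
AACGCTATGATGTACTATTTCGGTGACCACGGAGGATTATGCAAACCT
>IGKV7-S
ATAGGGTGGCCCGCACCCCATTTCGGCTCAGAAAATTGGAATGCTAATATCCCTCAGTTACCCTGTACGTCTATTCACAC
AGACGAATCCCTAGGGAATAACTTCACCAGAAATGAGATGATTACTCTAGCTGAAACATATTTATCGTATAGCAAATGGT
ATTTGGATATTAGGGAGACACGAGGAATGAAAATACGTGTATTTGGGCGCACGTGGACCTCGTTAATAGCGACAACGGAC
TTGGAACGAGCTGGGACAAGCCTCTTGTGGGGCATAATGTGCTTCAAG
>IGKV8-S
ATGCGGTGGATGCTCATGTCAAGACACAACTACATAGAGTGGCGGCGGGACGGTGAAATAATTTGCATCTTTGGGTCGGA
CCCCATTAAGCGTCGTAGAATTCCCACCTACGGAGCAACACTAATAGAGCCTGGTACCTGGAAGAAAACAAACTTCATGG
ATGATCAGCAGCAGCGGGGGAGCGAAAGAAAGGAGGACATTACTGCAAGTGATTATGAGTTGAACTACCGAGTCAAGCAC
TACCACCAGATGAACCATGGCGAGCTGTTCCCTGCCAAATGCTTCTTG
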