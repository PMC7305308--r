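>IGHD1-S
TTCCGTCTGGCCACTTTCC
>IGHD2-S
CCGGTAAGGGTGA
>IGHD3-S
CCTATAGTTATACCTCTATAC
>IGHD4-S
CATCCCCCCCAGTGTGA
>IGHD5-S
GCTTCGCGAGAAGCC
>IGHD6-S
TTAGACGTGCCACTGTTGGG
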