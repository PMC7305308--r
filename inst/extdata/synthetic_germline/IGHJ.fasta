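>IGHJ1-S
GAAACATGGTCCTCCGCGGTAGACTACGCGCAAAAAATGACAAACGTG
>IGHJ2-S
CAGTGCTGGAAGGTTAAGTGCAACTCACCTAGCTCCCATTGTGTCTAT
>IGHJ3-S
AAGCTGTGGGCAACTGCCTCGGATACGCAGATGATGGATCTTATGTGC
>IGHJ4-S
AATAGGTGGAATGAGTATTACTGCAAAACCAAATATTGCGGGACGCAG
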