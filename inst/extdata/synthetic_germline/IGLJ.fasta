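>IGLJ1-S
GCTGCGTTCAAACTTATGACACCTAATACGTGTACATCTAACAAGGTC
>IGLJ2-S
TACATGTTCACTATGTCGGAATGCCAAATGGCCAGCGCAGCGCCTTCG
>IGLJ3-S
CGAGAGTTTAAAAAATACCACACTATCATGGGCCATCAAGATCTTGAC
>IGLJ4-S
CCGGAGTTCTCCAAGGAAAAACCAGAGGGGAAAAACAGTGACGAAATT
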