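>IGKJ1-S
GTTAGGTTCGCCGTACCTGATTTACGACCGGTCTATATCATGTACTGT
>IGKJ2-S
TGTGGCTTTCAGGAGGAGAGTCTGCAATGCCAAACATATGGTATGATC
>IGKJ3-S
AGAATATTCCTGTTGAGCTGTACGATGCAGGAACGCGCTCCGGCGATA
>IGKJ4-S
GTCGTGTTTGGCATGATGATTGACTTAATTCCGGACAAATTGAATGTT
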