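# cdrseq

Alignment-free assembly of immunoglobulin CDR3 clonotypes from bulk RNA-Seq.

B cells diversify their antigen receptors by V(D)J recombination: variable
(V), diversity (D, heavy chain only) and joining (J) gene segments are
somatically joined, with non-templated nucleotides inserted at the junctions.
The third complementarity-determining region (CDR3) spans this junction —
delimited by a conserved cysteine at the end of the V segment and a conserved
phenylalanine (IGK/IGL) or tryptophan (IGH) at the start of the J segment —
and serves as the identity card of a B-cell clone: clones sharing an
identical CDR3 amino-acid sequence form one *clonotype*. Reads covering the
junction do not map to a reference genome, so standard RNA-Seq pipelines
discard exactly the reads that carry the repertoire signal. `cdrseq`
recovers them without alignment.

## Method

For every candidate read (unmapped reads and reads soft-clipped at the Ig
loci from a BAM, or raw FASTQ), translated in all six frames:

1. **Stage 1 — full CDR3 detection.** Enumerate putative spans
   `C … F/W` of 4–30 amino acids. Writing the read as
   *prefix* `r[0, x−1]`, *core* `r[x, y]`, *suffix* `r[y+1, n]`, a span is
   accepted when the prefix matches the pre-anchor substring
   `V_x = V[0, p_C−1]` of some V gene and the suffix matches the post-anchor
   substring `J_y = J[p_F+1, n_J]` of some J gene — each over the
   equal-length context window, requiring more than 4 residues of context and
   Levenshtein distance ≤ 1. All equally good gene hits are reported.
2. **Stage 2 — partial-CDR3 merging** (default for ≤ 50 bp reads). Reads
   matching only a V (or only a J) are merged pairwise on an exact
   nucleotide overlap of ≥ 15 nt, and the full core is re-extracted from the
   concatenation.
3. **CAST error correction.** Assembled CDR3s form a complete graph with
   edge affinity `1 / Levenshtein(x, y)`; partitions grow greedily from the
   max-weighted-degree node, adding nodes with mean affinity ≥ τ (default
   0.25) and removing members that fall below it. Each partition is reported
   as one clonotype with its count-weighted consensus sequence, V/J
   assignment, and — for IGH — the D gene sharing the longest exact
   substring (≥ 5 nt) with the CDR3 interior.

The package also ships a ground-truth simulator (germline sets,
V(D)J-recombined transcripts with junction insertions and exonucleolytic
trimming, substitution-error paired-end reads, decoy RNA-Seq mixtures),
exact-match precision/recall/F evaluation, and repertoire statistics:
clonotypes per million reads (CPM), Shannon α-diversity (bits),
Sørensen–Dice β-diversity, public/private sharing, and cell-type signature
scores.

## Worked example

```r
library(cdrseq)

germ <- read_germline_dir(system.file("extdata", "synthetic_germline",
                                      package = "cdrseq"), chains = "IGH")
tx   <- simulate_transcripts(germ, n = 50, chain = "IGH", seed = 5)
sim  <- simulate_reads(tx, read_length = 100, coverage = 16, seed = 6)
rep  <- profile_repertoire(sim$reads, germ, chains = "IGH")
rep
#> CDR3 repertoire profile
#>   input reads:       2954
#>   candidate reads:   2954
#>   clonotypes:        50
#>     IGH: 50
head(rep$clonotypes, 2)
#>   chain          cdr3_aa                                  cdr3_nt count frequency v_genes  d_gene j_genes
#> 1   IGH    CHTMTRPVERVEW  TGTCATACCATGACACGCCCCGTTGAGCGCGTCGAATGG     8     0.040 IGHV5-S IGHD6-S IGHJ4-S
#> 2   IGH CAVWDFTGAKSQFRMW TGCGCC...                                    7     0.035 IGHV3-S IGHD1-S IGHJ2-S
score_assembly(rep$clonotypes$cdr3_aa, unique(tx$true_cdr3_aa))
#>   tp fn fp recall precision f_score
#> 1 50  0  0      1         1       1
```

All 50 simulated clonotypes are recovered exactly (recall = precision = 1 at
100 bp reads and coverage 16); each row reports the consensus CDR3, its read
support and within-chain frequency, and the inferred V(D)J assignment.

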