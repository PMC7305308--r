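---
title: "Assembling immunoglobulin CDR3 repertoires from RNA-Seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assembling immunoglobulin CDR3 repertoires from RNA-Seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdrseq)
```

## The problem

Bulk RNA-Seq of any B-cell-containing tissue captures immunoglobulin
transcripts, but the reads spanning the V(D)J recombination junction do not
align to a reference genome: the junction contains non-templated N-region
nucleotides and heavily hypermutated sequence. Those unmapped (or
soft-clipped) reads carry the CDR3 — the hypervariable loop between the
conserved cysteine of the V segment and the conserved phenylalanine (light
chains) or tryptophan (heavy chain) of the J segment — which defines a
clonotype. `cdrseq` reconstructs the CDR3 repertoire from such reads without
any alignment step, using only anchored substring matching against a
germline segment set.

## Germline anchoring

Each V segment is translated in the frame of its reference sequence and the
*last* cysteine is recorded as the anchor `p_C`; each J segment's *first*
phenylalanine/tryptophan is the anchor `p_F`. The anchor splits each segment
into a pre-anchor and a post-anchor substring; stage-1 matching uses the
pre-anchor side of V (the sequence a read shows *before* the CDR3) and the
post-anchor side of J (what a read shows *after* it). Segments lacking the
anchor, or carrying a stop codon before it (pseudogenes), are excluded with
a warning — they cannot anchor a CDR3. All internal coordinates are 0-based;
IMGT alignment gaps (`.`) are stripped before translation.

A note on the J side: a literal reading of the anchor-split notation would
match the read suffix against the *pre*-anchor region of J, but that region
lies inside the CDR3 itself; the geometry of the junction requires the
post-anchor region, which is what this package matches against.

## Stage 1: full-CDR3 reads

Reads are translated in all six frames (ambiguous codons to `X`, stops to
`*`). In each frame every (C, F/W) index pair with a span of 4–30 aa and no
internal stop is a putative CDR3. The span is validated by its context: the
read prefix must be longer than 4 aa and within Levenshtein distance 1 of
the equal-length suffix of some `V_x`, and symmetrically for the suffix
against the prefix of some `J_y`. Because the comparison windows have equal
length, distance ≤ 1 reduces to at most one mismatch, which the compiled
scanner exploits; the R-level matchers use full dynamic programming and the
test suite proves the two routes identical on randomized instances
(the brute-force enumerator tries every frame, span, V and J).

Per read at most one candidate is kept: the span with the largest total
matched context, with ties broken by lexicographically smallest core, then
frame, then position — a deterministic rule, so identical inputs give
byte-identical outputs. When several germline genes tie at the best
distance, all are reported.

Design choices worth stating:

* **Six frames, not three.** Most bulk RNA-Seq protocols are unstranded;
  scanning the reverse complement doubles the work but maximises recall, and
  per-read deduplication makes it safe.
* **Length bounds 4–30 aa.** Suppresses spurious C..W pairs; 30 aa exceeds
  observed heavy-chain CDR3 lengths.
* **"More than 4" context.** Four residues of flanking germline context is
  the point at which a Levenshtein-1 match stops being informative; the
  strict inequality follows the method's published matching rule.

## Stage 2: partial-CDR3 reads

Short reads rarely contain a full CDR3 with enough context on both sides. A
read carrying only the V anchor (or only the J anchor) is held as a partial;
V-side partials are indexed by their 15-mers and each J-side partial whose
prefix exactly matches a V-side suffix over ≥ 15 nt is concatenated with it,
after which the full core is re-extracted and validated. The overlap must be
exact: allowing mismatches would invite chimeric fusions of fragments that
never came from the same molecule. Pairing is greedy, longest overlap first,
ties by read id, each read used at most once.

Stage 2 is enabled by default only when reads are ≤ 50 bp. At 75 bp the
merge buys little sensitivity and costs precision, and at 100 bp it buys
nothing — single reads already span the junction.

## CAST error correction

PCR and sequencing errors scatter low-count satellite sequences at edit
distance 1 around every true clonotype. Assembled CDR3s (aggregated by
identical amino-acid sequence, weighted by read count) form a complete graph
with affinity `1/Levenshtein`. Partitions are grown from the unassigned node
with maximal count-weighted affinity sum — in a complete graph plain degree
is constant, so weight is the only meaningful seed criterion — and refined
by alternately adding every node with mean affinity ≥ τ to the partition and
removing every member whose mean affinity to the rest falls below τ, until
stable. The add/remove dynamics can oscillate on borderline geometries; a
100-pass cap closes the partition as-is with a warning. Each partition
becomes one clonotype: the consensus restricts members to the length class
with the largest total count (ties to the shorter length) and takes the
count-weighted majority residue per position (ties alphabetical); gene
assignments keep the hits with maximal total weight.

τ defaults to 0.25 — the calibrated operating point of the underlying
method; thresholds below ~0.1 collapse closely related but genuinely
distinct clonotypes. The boundary is inclusive: two sequences at distance 4
(affinity exactly 0.25) still cluster at the default. Heavy- and light-chain
repertoires are clustered separately.

## D-gene assignment and reporting

For IGH clonotypes the representative nucleotide core (that of the
highest-count supporting read — the consensus is computed in amino-acid
space, so a nucleotide witness is kept alongside) is compared against the D
segments; the D sharing the longest exact substring with the CDR3 interior
(anchor codons excluded) is assigned, with a 5 nt floor below which matches
are indistinguishable from noise given 10–30 nt D genes. The report is a
deterministic TSV sorted by chain, descending count and CDR3, with optional
AIRR-style column aliases.

## The simulator

The generator exists to give the assembler a fully known truth. It emulates:

* **Recombination**: uniform V/(D/)J segment choice; non-templated
  insertions at each junction with truncated-Gaussian length, mean 15 nt and
  sd 4 nt;
* **Junctional processing**: exonucleolytic trimming of the joining ends
  (V 3′, both D ends, J 5′), |N(4, 3)| nucleotides capped so the anchors
  survive. Trimming is standard V(D)J biology and, combined with the 15 nt
  insertions, yields CDR3s averaging ~16 amino acids — the length range
  reported for real heavy-chain repertoires. Without it the simulated CDR3s
  would average over 21 aa, longer than real repertoires show;
* **In-frame selection**: transcripts whose junction shifts the J anchor out
  of the V reading frame, or whose CDR3 span contains a stop, are rejected
  and redrawn — mirroring the exclusion of out-of-frame products;
* **Clone-size skew**: abundances follow a power law over rank (exponent 1,
  Zipf; 0 gives uniform);
* **Sequencing**: paired fragments placed uniformly, substitution errors at
  0.1% per base (indels are rare on the platforms this models and are not
  simulated). Coverage is defined as the expected per-base depth from all
  mates: a transcript of length L receives `round(c·L/l)` mates. Every
  transcript is covered at the nominal coverage; abundance-proportional
  coverage is available as an option but is not the default, since the
  evaluation design treats coverage as a per-transcript axis;
* **Background**: decoy reads drawn from random transcripts with human-like
  GC (42%), lengths 500–3000 nt, standing in for a reference transcriptome
  (a real FASTA can be supplied instead).

What the simulator does *not* model: somatic hypermutation lineages,
isotypes, empirical quality profiles, indel errors, allele-level germline
variation. Passing tests therefore demonstrate correctness of the assembly
and clustering machinery under a clean generative model, not performance on
real tissue RNA-Seq.

The bundled germline fixture is itself synthetic (random codons around
planted anchors, labelled `-S`), so the whole test suite runs without any
downloads; loaders accept real IMGT files with pipe-delimited headers and
gap characters.

## Evaluation design and expected operating characteristics

Scoring is clonotype-level and exact-match: TP/FN/FP over distinct CDR3
amino-acid sequences, recall TP/(TP+FN), precision TP/(TP+FP), F the
harmonic mean. The acceptance analyses use 200 transcripts per run, read
lengths {50, 75, 100} × coverages {8, 16, 32} with three replicate seeds,
and a 1:100 decoy mixture for the extraction endpoint — sizes chosen to keep
a full desk run in minutes while leaving each cell's estimates stable to a
few percent.

Two geometric facts shape the results. First, extraction of junction reads
into the candidate set is nearly lossless (the intake filters only remove
low-quality and low-complexity reads), so extraction recall sits at ~100%.
Second, stage 1 requires a read to contain the whole CDR3 *plus* 15 nt of
context on each side. With ~16 aa (~50 nt) CDR3s this fits easily in 100 bp
reads (recall ≥ 90% once coverage exceeds ~8), marginally in 75 bp reads
(only short CDR3s qualify, so recall drops sharply), and essentially never
in 50 bp reads — where stage 2's overlap merge recovers a substantial
fraction. Precision is high everywhere (~95–100%): CAST absorbs the
substitution-error satellites, and spurious spans almost never survive
two-sided context matching. The grid-average F-score is therefore dominated
by the 75 bp column's recall penalty; this is an inherent property of strict
two-sided containment at that read length, not a tuning artifact.

## Numerical and degenerate-input conventions

* Coordinates 0-based half-open internally; 1-based only in logs and TSVs.
* Ambiguous translation (`X`) never matches any germline residue.
* Empty inputs flow through: an empty read set yields an empty repertoire
  with a warning, never an error.
* All randomness is seed-controlled; identical seeds give byte-identical
  transcripts, reads, manifests and clonotype tables.
* α-diversity is reported in bits (base-2 entropy): reported spleen-scale
  diversities (α ≈ 7.6 at ~1000 distinct clonotypes) exceed the natural-log
  ceiling ln(1025) ≈ 6.9, so base 2 is the only consistent convention.
* β-diversity is computed on amino-acid clonotype sets, and samples with
  fewer than ten reported clonotypes are excluded from pairwise comparisons.

## Known limitations

* T-cell receptors, paired heavy/light inference and isotype calling are out
  of scope.
* Read pairs are treated as independent single-end reads; no mate-aware
  rescue is attempted.
* The clonotype read counts are integers per supporting read; no fractional
  multi-mapping weights.
* The 75 bp recall ceiling discussed above.
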