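---
title: "Integrated lncRNA, poly(A)-site and small-RNA profiling with lncstar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated lncRNA, poly(A)-site and small-RNA profiling with lncstar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncstar)
```

# Scope and model

`lncstar` re-implements, as tested library code, the downstream integration
steps of a multi-assay nutrient-starvation transcriptome study in a cereal:
strand-specific RNA-seq assemblies are mined for novel long non-coding RNAs
(lncRNAs), 3′-tag (2P-Seq) data refine and diversify their 3′ ends,
expression is profiled over a two-tissue × five-timepoint design, degradome
tags validate miRNA cleavage targets, and small-RNA signal at cis-natural
antisense transcript (cis-NAT) pairs is attributed to its strand of origin.
Read alignment and transcript assembly are out of scope: the package
consumes transcript models (GTF), a genome (FASTA), position-level 5′-tag
files (BED6) and count tables (TSV).

All genomic positions are held internally in 0-based half-open coordinates
(BED-compatible); GTF/GFF3 conversion happens once, at the IO boundary.
Tags on the `-` strand take `end − 1` as their biological 5′ end. 2P-Seq
tags are assumed to be orientation-corrected to the transcript strand by the
upstream aligner; no protocol-level strand flipping is applied.

# lncRNA discovery

Discovery is a strict filter cascade:

1. **Novelty.** Any assembled transcript with ≥ 1 bp of *same-strand*
   exonic overlap with the reference annotation is removed. Antisense and
   intergenic transcripts survive by construction.
2. **Length and expression.** Exonic length ≥ 200 nt (the community lncRNA
   floor) and FPKM > 1.0 in at least one sample. The exact thresholds used
   in the original analysis are not published; both are configurable and the
   defaults mirror the study's own "expressed" convention (> 1 FPKM).
3. **Coding potential.** Support-vector classifiers with BLAST-derived
   features are replaced by a deterministic, dependency-free composite:
   `S = 0.3·min(ORF/300, 1) + 0.2·(ORF/L) + 0.5·H`, where ORF is the longest
   ATG…stop frame (stop required, length includes the stop codon, three
   forward frames) and `H` the best shared peptide 4-mer fraction between
   any of the six frame translations and any reference peptide
   (|shared| / |query 4-mers|). `S ≥ 0.5` is called coding; a tie goes to
   *coding*, the conservative direction for lncRNA discovery. The 300-nt
   pivot corresponds to the classical 100-codon ORF heuristic.
4. **Dual-reference rescue.** Scoring runs twice: against the full protein
   reference and against a taxon-excluded subset. Noncoding under the full
   reference → RLC (relatively low coding potential). Coding under the full
   reference but noncoding once within-taxon peptides are excluded → RHC
   (relatively high coding potential, "rescued": its only support was a
   short, non-conserved within-taxon peptide). Coding under both →
   discarded. This two-pass rescue is the scientific core of the discovery
   module.
5. **Loci.** Survivors are merged by single-linkage same-strand exonic
   overlap (the original merging rule is unpublished; single linkage is the
   least committal choice). A locus is *cis-NAT* when **any** member has
   ≥ 1 bp opposite-strand exonic overlap with an annotated transcript, else
   *intergenic*. A locus with any RLC member is labelled RLC; only loci
   whose every member was rescued are RHC — low coding potential is the
   stronger evidence for the lncRNA call. Identifiers follow `<chrom>Gnnnn`
   in per-chromosome coordinate order.

# 2P-Seq poly(A) sites and APA

Tag counts are accumulated per exact position, then clustered by single
linkage with a 24-nt gap bandwidth and a 5-tag cluster floor (both
configurable; the original peak rule is unpublished, and these values sit
comfortably between tag jitter and the ~100 nt scale that separates truly
distinct sites). The peak mode is the position of maximal count, ties
resolving to the most 3′ position on the strand. A peak is a candidate
poly(A) site for the *nearest* same-strand transcript 3′ end within 1000 bp
(signed distance measured along the strand, positive downstream — the 1-kb
window is the one stated rule of the source analysis). Loci retaining ≥ 2
assigned peaks ≥ 100 nt apart (closer peaks merge into the stronger one)
yield APA calls; 100 nt rejects jitter while detecting the ~1 kb separations
reported for real dual-site loci. 3′ ends are refined to the strongest
assigned peak, never crossing a same-strand annotated neighbour and never
emptying the terminal exon. No internal-priming (A-rich) filter is applied
by default since 2P-Seq primes on the poly(A) tail itself.

# Expression profiling

FPKM uses exonic length and per-sample fragment depth; RP40M (reads per 40
million) is the small-RNA unit. Fold changes are `log2((a + ε)/(b + ε))`
with ε = 0.1 expression units (the source states no pseudocount; 0.1 is one
order below the expression floor and leaves > 2-fold calls of expressed
features essentially untouched). A feature is *up*/*down* in a contrast when
|log₂ FC| ≥ 1 **and** the larger of the two values reaches the 1.0 floor —
the study's "> 2-fold in at least one condition" rule, with the floor
guarding against ratio noise at trace expression. Root/shoot direction
pairs map deterministically to
concordant-up/concordant-down/discordant/root-only/shoot-only/none, and
responsive sets are intersected across conditions with exact set algebra.
No replicate-based statistical testing is performed — the profiled design
has one library per tissue × timepoint, so inference is fold-change-based by
construction. Heatmap clustering is left to general-purpose tools; the
package exports the matrices.

# Degradome target calling

The aligner scans every ungapped register and every single internal bulge
(1–2 nt, miRNA or transcript side) of the reverse-complemented miRNA:
Watson-Crick match 0, G:U wobble 0.5, mismatch 1.0, each bulged nucleotide
1.0, all doubled at miRNA positions 2–13 — the plant-target scoring
convention compatible with a "score ≤ 5.0" reporting threshold. A bulged
transcript nucleotide takes the position of the next miRNA base toward the
3′ end. The predicted cleavage site is the transcript base opposite miRNA
position 10 (the 10–11 scissile register); alignments bulged at position 10
are rejected for cleavage prediction. Degradome support is categorised on
raw counts: 0 unique transcript maximum, 1 shared maximum, 2 above the
median of occupied positions, 3 at/below it, 4 single read. The p-value
permutes the miRNA by Altschul–Erickson dinucleotide shuffling (N = 100 by
default) and compares the best (category, penalty) pair achievable by each
shuffle on the same transcript, so p = 1/(N+1) is the attainable floor. The
original pipeline delegated significance to an external tool whose null is
unpublished; equality of p-values is therefore not asserted anywhere —
super-uniformity under the null is, and is property-tested.

# cis-NAT small-RNA attribution

The qualitative argument "strand-specific small-RNA abundance tracks the
expression of the matching single-stranded transcript" is made quantitative:
per-sample strand totals over the overlap region are RP40M-normalised and
Pearson-correlated with the strand-matched partner's FPKM across the
10-sample design (Spearman by flag). The verdict requires the winning
correlation ≥ 0.7 with a ≥ 0.2 margin; anything weaker is *ambiguous*,
which is also the representation of a double-stranded (paired-duplex)
origin — no duplex model is fitted. The thresholds are this package's own
(the source defines none) and are configurable.

# The synthetic world

`simulate_nstarve()` generates, deterministically per seed, a 500-kb
chromosome carrying 60 two-exon coding genes and 30 noncoding loci — 15
intergenic and 15 antisense, 8 of them two-exon so that ~73% of loci are
single-exon, matching the reported preponderance of single-exon lncRNAs.
Seven noncoding loci are exact CDSs of short (66-aa) peptides present only
in the full protein reference, making them RHC rescues by construction; the
remaining 23 are random-sequence RLC loci (the probability that a random
600-nt sequence clears the coding cutoff is ≪ 10⁻³ and is accepted as a
residual stochastic risk rather than rejected away). Antisense loci overlap
exactly 100 nt of their host's 3′ UTR — never the CDS — so their
coding-potential scores stay honest.

Counts are negative-binomial (size 80) around log-normal baselines
(meanlog = log 200, sdlog = 0.5) at depth 2·10⁷, the minimal over-dispersed
bulk RNA-seq model; planted effects are signed log₂ fold changes drawn from
[1.5, 3] for 30% of features (plus all NAT partners, whose profiles must
vary for attribution to be identifiable), applied at every treated
timepoint. The floor of 1.5 keeps planted effects comfortably above the
2-fold calling threshold, as the generator contract requires (a planted
|lfc| of exactly 1 would be recovered only half the time). 2P-Seq sites get
200 tags with integer-rounded Gaussian jitter (sd 5 nt) over a 0.2 tags/kb
uniform background; the 4 APA loci carry a second site 300 nt upstream with
60% tag weight. miRNAs are exact reverse complements of planted 3′-UTR
sites, then mutated by fixed recipes to penalties {0, 1.5, 3, 5} so the
score threshold is exercised at both ends; 60% of a target's 50 degradome
tags sit exactly on the cleavage site. Two decoy miRNAs have no planted
sites.

What the generator does **not** emulate: read-level errors, mappability and
multi-mapping artefacts, internal priming, isoform mixtures within a locus,
batch effects, and replicate structure. A green planted-truth test therefore
establishes correctness of the computations on well-posed inputs, not
robustness to alignment pathology.

# Numerical and design notes

* Ties at the coding cutoff are called coding; ties for the peak mode go to
  the most 3′ position; peak-to-transcript assignment ties go to the
  lexicographically smallest transcript id. All tie rules are deterministic
  so that identical seeds give byte-identical outputs end to end.
* The permutation p-value uses `(1 + b)/(1 + N)`, never 0, and is
  deterministic given the seed; each miRNA gets an independent sub-seed.
* Pipeline logs omit wall-clock timestamps: run reproducibility
  (byte-identical reruns) was judged more valuable than timing banners.
* Degenerate inputs: empty tag sets, loci with no surviving transcript,
  transcripts missing from the expression matrix, and sub-3-sample
  attribution all fail fast with classed, named errors rather than
  propagating NAs.

# Limitations

The coding-potential scorer is intentionally simple; it preserves the
dual-reference rescue logic but is not a drop-in replacement for SVM-based
classifiers on real proteomes. Degradome p-values follow this package's
documented null, not the external tool's. APA is detected, not quantified
across conditions. Headline counts from the motivating study (thousands of
loci from hundreds of millions of reads) are not reproducible at desk scale;
the test suite instead verifies every computation against brute-force
oracles and planted truth.
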