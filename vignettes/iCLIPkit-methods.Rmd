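---
title: "iCLIPkit: models and methods"
author: "iCLIPkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{iCLIPkit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

iCLIPkit implements a complete analysis path for individual-nucleotide
resolution CLIP (iCLIP) data, from raw barcoded reads to candidate
splice-switching oligonucleotide (SSO) targets, together with a seeded
synthetic-data generator that provides ground truth for every stage. This
vignette describes the underlying models, the parameters that matter, and
the design decisions taken where more than one reasonable choice existed.

# The iCLIP signal model

In iCLIP, reverse transcription usually terminates at the nucleotide
crosslinked to the protein, so the crosslink site is taken to be the base
immediately 5' of the read start in transcript orientation. A minority of
cDNAs read through the crosslink and instead carry a short deletion at the
crosslinked base; for those reads the deletion site is the crosslink. Both
signal types are implemented:

* no deletion: site = alignment start − 1 (plus strand) or alignment
  end + 1 (minus strand);
* with deletions: site = the 5'-most deletion position in transcript
  orientation. Multiple deletions in one read are rare and the rule is
  deliberately simple; the generator only ever produces one deletion run.

The minus-strand convention is not observable from a single read in
isolation; it is fixed by the round-trip property that the simulator's
planted crosslinks are recovered exactly on both strands
(`assignCrosslinks()` tests).

A read-start concordance diagnostic (`startProfileDiagnostic()`) checks the
truncation assumption on real data: genuinely truncated libraries show the
same 5' starts for short (20–35 nt) and long (41 ± 1 nt) fragments. The
genome is tiled into 300-nt windows, windows with fewer than 20 fragments
are skipped, and the modal start offset between the two length classes is
reported per window; the library is called start-concordant when the modal
offset across windows is 0.

# Preprocessing and PCR-duplicate collapsing

Reads carry a 9-nt 5' barcode laid out as `RRRIIIIRR`: five random
positions (the PCR tag) interleaved with a 4-nt sample identifier. The R
bases are stitched, in read order, into a 5-nt random tag that travels in
the read name (`#TAG`) so that any aligner preserves it. Demultiplexing
requires an exact identifier match: identifiers are only 4 nt, so allowing
mismatches would misassign reads at an appreciable rate.

The trimming stack is: 3' running-sum quality trimming at Q20, then 3'
adapter trimming (longest terminal occurrence of an adapter prefix,
minimum 3 nt overlap, at most one mismatch, no indels; internal
full-length occurrences truncate from the match start), then a ≥ 20 nt
length filter. The quality threshold and overlap floor are package
defaults, exposed in `pipelineConfig()`; the one-mismatch allowance and
the 20-nt filter are fixed points of the protocol.

Duplicates are collapsed per (chromosome, strand, 5' alignment start,
sample). Grouping on the 5' start rather than the full span is deliberate:
3' trimming makes fragment ends variable between copies of the same
molecule. Within a group, tags at Hamming distance ≤ 1 are "the same
molecule". Treating this relation transitively is a choice — the relation
itself is not transitive — and the default is connected components of the
distance-≤ 1 graph, which is order-independent and reproducible; a greedy
non-transitive mode (`greedy = TRUE`) is provided for comparison. The
representative of each component is the record with the lexicographically
smallest tag (earliest on ties), another determinism guarantee. With 5-nt
tags, distinct molecules at one position collide within distance 1 with
probability 16/1024 per pair, so molecule counts are slightly conservative
at high per-position depth; the component count equals the true molecule
count whenever true tags are pairwise at distance ≥ 3.

# Peak calling

Each crosslink site is extended by ±10 nt into a 21-nt binding region;
overlapping same-strand regions merge into candidate peaks per gene (genes
span their full pre-mRNA extent, introns included; genes overlapping on
opposite strands are handled independently because the assay is
strand-specific). Significance is assessed against a *superlocal* null:
the candidate plus 500 nt on each side (≈ 1 kb total), clipped to the
gene, defines the background window, which absorbs local coverage bias.
Under the null, the window's total molecule count is redistributed
uniformly over its positions; the test statistic is the maximum 21-nt
sliding-window count. With `n_permutations` draws (default 1000, seeded),

$$p = \frac{1 + \#\{\text{null max} \ge \text{observed max}\}}{n + 1},$$

which can never be exactly zero. The observed maximum is computed over
windows anchored in the candidate, while the null maximum is over the
whole background window, making the test slightly conservative. P-values
are Benjamini–Hochberg adjusted across all candidates in the run (the
transcriptome-wide choice; a per-gene adjustment would be anti-conservative
for genes with few candidates), and peaks at FDR ≤ 0.10 are significant.
This module is a documented stand-in for the external caller used in the
original protocol: it implements the named ideas (superlocal ~1-kb
windows, randomisation p-values, pre-mRNA extent, FDR 0.1) without
claiming equivalence to that tool's internals; no transcriptome-wide
Poisson cutoff is applied.

# Motif analysis

Motif work is done on the sense strand only. Enrichment is exact k-mer
counting (k = 6, 7, 8) in peak sequences versus a background set, with a
one-sided binomial p-value against the background occurrence rate, 0.5
pseudocounts per cell for rates and folds, and BH adjustment per k. The
default background is a dinucleotide-preserving (Eulerian-walk) shuffle of
the foreground, which controls for CpG-like composition; an i.i.d. uniform
generator is available as the simpler alternative. This replaces the
multi-mismatch merging and multi-length optimisation of dedicated motif
finders with a transparent, testable procedure; the frequency matrix is
built from occurrences of the top k-mer and its 1-mismatch neighbours in
the foreground.

Scoring matrices are `log2((f + p) / (0.25 + p))` per position and base
with pseudocount `p = 0.001`; with `p = 0` the limits are exactly 0 bits
at the 0.25 background and 2 bits for a fixed base, and the pseudocount
only prevents −∞ at zero frequencies. Window scores are sums of position
scores; variant effects are the difference in the best window overlapping
the variant (alt − ref), so negative deltas predict disrupted binding.

# Splicing quantification

Cassette-exon inclusion is quantified from junction counts as
PSI = inclusion / (inclusion + exclusion), NA when both counts are zero.
Condition PSI is the mean over quantifiable replicates;
`log2fc = log2((PSI_kd + 0.01) / (PSI_ctrl + 0.01))` with 1%
pseudoinclusion added to each condition. Significance uses a two-sided
Fisher exact test on counts pooled across replicates, BH-adjusted, with
FDR < 0.1 events classified by direction: inclusion up on knockdown means
the factor *represses* the exon. Pooling ignores replicate overdispersion
and will be anti-conservative when replicates disagree strongly; this is a
documented simplification (a beta-binomial extension point exists in the
design but is not the default), and the calibration test shows the
realised type-I error under binomial replicate noise stays below the
nominal level.

Splice-site strength comparisons (activated/repressed vs neutral, per site
type) use two-sided Wilcoxon rank-sum tests. The scorer is pluggable: the
built-in is a first-order position-weight matrix trained on the
annotation's own donor (exon −3 … intron +6) or acceptor
(intron −20 … exon +3) windows, which exercises the machinery but is not a
maximum-entropy model; an external scorer with the same signature can be
substituted. GC content is compared per exon and per 100-nt flank the same
way.

# Genomic distribution and metagene profiles

Sites are assigned to one region each with precedence
CDS > 5'UTR > 3'UTR > intron > intergenic, computed on the transcript with
the most exonic sequence per gene; the precedence is a package decision
(the protocol source does not state one) and is the conventional one.
Densities are per-kb of total region length. Metagene profiles map sites
into an unscaled 100-nt 5' flank, a body scaled to `body_bins`, and an
unscaled 100-nt 3' flank, in transcript orientation (minus-strand regions
mirror exactly); densities are per million input sites. The 95% band is a
seeded percentile bootstrap over *regions*, not sites, so correlated sites
within one region do not artificially narrow it; the band is clamped to
contain the point estimate. Flanks of adjacent regions may overlap for
closely spaced regions; no double-counting correction is applied beyond
the region-set choice.

# SSO target selection

Candidate targets are peaks whose nearest edge lies 10–40 nt downstream of
the donor site of a repressed cassette exon (or a user-supplied
pseudoexon), measured from the first intronic base (distance 1), both ends
inclusive. Peaks closer than 10 nt would overlap the donor recognition
region; peaks beyond 40 nt are too distal to block effectively. Candidates
are ranked by (sum of motif-hit scores in the target window) ×
log2(1 + peak height) — a labelled heuristic combining motif content and
binding strength, exposed rather than hidden, since no quantitative
ranking rule is established. The proposed SSO is the reverse complement
(in RNA) of the shortest 18–25-nt window covering the window's motif hits,
padded symmetrically to the minimum, clamped with a warning at the
maximum, and never overlapping the 9-nt donor region (exon −3 …
intron +6).

# The synthetic-data generator

`simulateGenome()` builds genes of 3–5 exons (80–200 nt) separated by
introns (200–800 nt) on alternating strands, with i.i.d. uniform ACGT
background sequence (so every base is at the 0.25 scoring background).
Half the genes carry a cassette middle exon skipped by a second
transcript. True crosslink sites (5 per gene, ≥ 50 nt apart) receive
Poisson(20) molecules each and, at rate 0.6, the UAGGGA consensus written
immediately downstream of the crosslink; single-molecule background events
are scattered at 1 per kb. `simulateIclipReads()` truncates molecules at
the crosslink with probability 0.85 and otherwise reads through leaving a
1–2 nt deletion (both code paths exercised; the real mixture rate is not
established, so the default is a package choice), emits
1 + Poisson(3) PCR copies per molecule with tag substitutions at 1% per
base, prefixes the RRRIIIIRR barcode, and appends adapter when the
fragment (35–50 nt) is shorter than the machine read length. True
alignments are emitted directly so no aligner is required; an
exact-substring aligner exists only for error-free smoke tests.
`simulateJunctionCounts()` draws inclusion counts Binomial(depth 100) at
the configured PSI per replicate (3) and condition (control 0.5 vs
knockdown 0.8 by default — a 0.3 inclusion shift).

What the generator does *not* emulate: realistic base-quality error
models, empirical fragment-length distributions, mappability structure,
multi-mapping reads (tested via hand fixtures instead), overdispersed
junction counts, and composition bias beyond i.i.d. background. Passing
tests therefore demonstrate correctness of the algorithms under the
stated statistical model, not performance on real libraries.

# Numerical choices and problem sizes

All randomness is driven by integer seeds; derived stream seeds stay below
2^31. Ties in modal offsets and in duplicate representatives resolve to
the smallest value. Permutation p-values use the +1/(n+1) estimator.
Degenerate inputs (empty site sets, empty groups, exons at contig edges,
both-zero junction counts) return empty results or flagged NA rather than
errors, except where the input is malformed, which always errors.

The shipped validation suite runs at deliberately desk-sized scales: 8–25
genes for pipeline round-trips (≈ 10⁴ reads), 100 genes × 10–20 seeds for
null calibration of the peak caller at 200 permutations, 200 peaks × 20
seeds for motif recovery, and 200 exons for splicing calibration and
power. These sizes give tight Monte-Carlo control of the quantities
checked while keeping the whole suite inside a coffee break; all
thresholds were fixed from the statistical model, not from observed runs.

# Known limitations

* Molecule counts are slightly conservative at very high per-position
  depth (5-nt tag collisions).
* The Fisher-on-pooled-counts splicing test ignores replicate
  overdispersion.
* The built-in splice-site scorer is a first-order PWM, not a
  maximum-entropy model; use the pluggable interface for serious
  strength analyses.
* The peak caller is a stand-in for the external tool named in the
  protocol; equivalence is not claimed.
* Region precedence and the metagene flank handling are conventions, and
  alternatives (e.g. per-isoform profiles) are out of scope.
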