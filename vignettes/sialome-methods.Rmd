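---
title: "Methods: from EST library to divergence, volatility and phylogenies"
author: "sialome package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from EST library to divergence, volatility and phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sialome)
```

This vignette explains what each stage of the package computes, the
assumptions behind it, the tunable parameters and their defaults, and what
the synthetic-data generator does and does not emulate.

## The study design the package models

A sialotranscriptome study sequences a few thousand single-pass cDNA reads
(ESTs) from the salivary glands of a blood-feeding insect. The
computational analysis groups reads into clusters representing transcripts,
deduces proteins, separates housekeeping (H) from putatively secreted (S)
machinery, and then asks evolutionary questions: do secreted salivary
proteins diverge faster than housekeeping proteins between related species,
and is their codon composition more "volatile"? The package implements that
analysis as reusable, tested functions, with a generator that produces
inputs of known structure so every stage can be validated without any
external database.

## EST clustering

`cluster_reads()` links two reads when they share an exact word of
`word_size` nt (default 36) that seeds an ungapped overlap of at least
`min_overlap` nt (default 40) at `min_identity` (default 0.80) — the
classic blastn-word + CAP3-threshold combination for Sanger EST assembly.
Clusters are the connected components of the accepted-overlap graph
(single linkage). Full overlap-layout-consensus assembly is deliberately
out of scope: transitive clustering reproduces the cluster/singleton
bookkeeping that downstream abundance analysis needs, which is the level
at which EST studies report their assembly. Identity is computed over
non-`N` columns only (`N` is missing data, not mismatch), overlaps are
ungapped (gapped overlap extension is future work),
and only forward-strand overlaps are sought because the libraries modelled
are unidirectional.

The consensus is a greedy layout by the accepted pairwise offsets with a
per-column majority vote, ties broken in fixed base order A < C < G < T. A
layout conflict (an overlap edge disagreeing with the positions already
fixed) drops the conflicting edge with a warning; on error-free input
conflicts cannot arise, and the oracle tests exploit exactly that.

## ORF selection, secretion, classification

`three_frame_translate()` translates the three forward frames under the
standard genetic code. `select_orf()` takes, per frame, the segment from
the first methionine within the first 300 predicted residues to the first
following stop, and reports the longest candidate across frames (ties to
the lower frame). The 300-residue window is the conventional guard against
spurious late starts in 5'-truncated ESTs.

`predict_secretion()` is a deliberately transparent stand-in for a trained
signal-peptide predictor: it requires, within the first 30 residues, an
uninterrupted hydrophobic run of at least 8 residues followed within 10
residues by a small residue (a cleavage-like site). Both thresholds are
arguments. A trained predictor cannot be faithfully re-implemented here,
so the classification cascade lets a `signal_peptide` column in the
evidence table (i.e., a real predictor's output) override the heuristic —
the pipeline contract is preserved either way.

`classify_record()` applies a first-match-wins cascade: explicit curator
hint, then secretion + secreted-family keyword match (or no informative
hit → S/unknown), then housekeeping keyword match, else Unknown. The
keyword vocabularies (19 H subgroups, 24 S families) ship as editable TSVs
under `extdata`. This is an explicit approximation: the studies this
package models classified transcripts after manual inspection of many
database searches, and no rule set can reproduce curation exactly. The
cascade is deterministic and order-independent, which is what the tests
hold it to.

`category_table()` reports EST-weighted counts, percent of library per
class and percent of group per subcategory, half-up rounded to one decimal
(base R's round-half-even does not reproduce published tables).

## Cross-species identity

`class_identity()` aligns each query protein against a reference proteome
with affine-gap local alignment (BLOSUM62, gap open 11 / extend 1 — blastp
defaults; `Biostrings::pairwiseAlignment` provides the dynamic program,
and tests pin its scores to an exhaustive small-case enumeration oracle).
The best hit is the highest-scoring alignment, mirroring blast ranking;
queries whose best alignment spans fewer than 100 aligned columns are
excluded; class means are plain averages of percent identity; and the two
class samples are compared with a two-sided Mann-Whitney rank-sum test
(exact by enumeration when n1+n2 ≤ 12 without ties, else the
continuity-corrected normal approximation). `X` scores 0 against
everything and never counts as an identity.

`dedup_alleles()` removes putative alleles/recent duplicates before the
class comparison: visiting pairs in descending length order, it drops the
shorter sequence of any pair whose similarity reaches 0.80. Similarity is
blast-style positives from the best local alignment taken **relative to
the shorter sequence's length**. Positives over local-alignment columns
alone would be degenerate — an optimal local alignment is mostly positive
pairs by construction, so nearly every pair would exceed 0.80; anchoring
the denominator to the sequence restores the intended meaning of "80%
similar to another member of the set". Strict identity can be used via
`use_identity = TRUE`.

Open choices resolved here: the best single local alignment (not
concatenated HSPs) feeds the identity; the dedup threshold applies to
positives, not identities, with the identity variant available.

## Codon volatility

`codon_volatility()` computes, for a sense codon, the fraction of its nine
single-nucleotide neighbors encoding a different amino acid; neighbors
that are stops are removed from the denominator (set
`count_stop_neighbors = TRUE` to keep them, for sensitivity analysis).
Under the standard code the values span (0.5, 1.0], and exactly ATG and
TGG — the two single-codon residues — reach 1.0. The whole table is pinned
to an independent brute-force enumeration in the tests.

`gene_volatility()` is the unweighted mean over a gene's sense codons
(stops and `N`-containing codons are skipped and counted in QC
attributes); `compare_class_volatility()` reports per-class means and
standard errors over genes (not codons) and a Welch two-sample t test —
Welch rather than pooled because class variances need not match; pooled is
a flag. Reporting SE over genes and entering genes unweighted by length
match how class-level volatility summaries are conventionally quoted.

## Cross-library abundance

`pooled_expected()` estimates a single pooled rate across libraries and
the per-library expected counts; `chi_square_gof()` tests homogeneity
either as the 2 × k class/non-class contingency table (default, df = k−1,
uncorrected) or over the class cells alone. Both modes are exposed with
all intermediate values because published chi-squares of this kind rarely
state their cell set: on the apyrase counts shipped in the examples
(1/503, 99/4066, 66/4232, 0/1753) the two modes give 53.7 and 52.8 —
consistent with, but not equal to, the historically printed 54.6, whose
exact arithmetic is not reconstructible from the printed counts. The
package documents this rather than tuning to match. Expected cells below 1
set a validity flag instead of refusing.

## Phylogenies

`protein_distance()` offers p-distance and Poisson-corrected distance with
pairwise deletion of gap/`X` columns (complete deletion would discard data
unevenly across a ragged family alignment). `nj_tree()` is the
Saitou–Nei neighbor-joining agglomeration with the standard Q criterion
and branch-length formulas, deterministic tie-breaking by smallest
representative leaf label, and clamping of negative branch estimates to
zero (count recorded as an attribute). On additive matrices it returns the
generating tree exactly; tests verify this up to 12 taxa, against an
independent NJ implementation, and against an all-topology least-squares
oracle at 6 taxa. `bootstrap_support()` resamples alignment columns with
replacement, rebuilds the NJ tree per replicate, and reports bipartition
frequencies as integer percents in the node labels; 1,000 replicates by
default (large published phylograms use 10,000 — identical semantics, just
more replicates), always reproducible from the seed.

## The synthetic-data generator

`synthetic_config()` fixes the study conditions: a 1,753-read library from
a Zipf-skewed transcript pool (`p_i ∝ i^-alpha`, alpha = 1), Sanger-like
read lengths (mean 500 nt, sd 80), 1% substitution errors (indels off by
default so the clustering oracle stays exact), 169 housekeeping and 50
secreted ortholog pairs at 91.2% and 70.1% target identity (sd 0.05,
300 aa), 205 + 80 coding genes of 400 codons tuned to class volatilities
0.761 and 0.775, and an 8-member protein family — the sizes at which the
analyses it feeds were originally reported. Every generator is a pure
function of (parameters, seed) and emits its ground truth (read positions,
realized identities, generating trees).

What the generator does **not** emulate: sequencing chimeras and vector
contamination, quality values, indel errors (available but off),
non-uniform codon usage along genes, rate heterogeneity across protein
sites, and any real database of homologs. Passing tests therefore show
that the pipeline's arithmetic and inference are correct under the stated
statistical structure — not that the heuristics (e.g., the secretion rule)
would match trained predictors on real proteins.

Ortholog substitutions are uniform over the 19 alternative residues — the
simplest model that makes identity recovery testable; matrix-based
evolution is a non-goal. Coding-gene volatility targets are reached by
blending uniform codon usage with a point mass on an extreme-volatility
codon (`codon_usage_for_volatility()`); the initiator ATG adds a known,
tiny offset ((1 − target)/(n_codons + 1)) that the tests account for.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the volatility recovery at
205 + 80 genes × 400 codons, the identity recovery at 219 pairs × 300 aa
(each query searched against all 219 references), NJ checks up to 12 taxa
(all-topology oracle at 6), and bootstraps at 40–1,000 replicates — sizes
chosen so the whole suite completes in a few minutes on one core while
keeping every estimate's Monte-Carlo error well inside its stated
tolerance. Tolerances follow from the generating process (binomial/CLT
standard errors), never from the observed output. Degenerate inputs are
handled explicitly: zero-variance t tests fall back to an
epsilon-floored statistic, all-identical Mann-Whitney samples return P = 1
with a degeneracy flag, saturated Poisson distances (p = 1) and
stop-codon volatility are errors by design.

## Known limitations

Single-linkage clustering can chain distinct transcripts through a shared
repeat (no chimera detection); the secretion heuristic is a coarse filter,
not SignalP; keyword classification cannot reproduce manual curation;
identity is taken from the best local alignment only; JTT-style corrected
protein distances and gapped overlap extension are not implemented.
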