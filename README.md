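# sialome

Analysis toolkit for salivary-gland EST (sialotranscriptome) studies of
blood-feeding insects.

A sialome study sequences a few thousand single-pass cDNA clones from
salivary glands, clusters them into transcripts, deduces the encoded
proteins, and splits the catalogue into housekeeping (H), putatively
secreted (S) and unknown (U) classes. The evolutionary questions that
follow — do secreted salivary proteins diverge faster between related
mosquito species than housekeeping proteins, and is their codon
composition more volatile? — need a reproducible computational pipeline.
This package provides that pipeline as tested R functions:

- **EST clustering**: exact-word seeded ungapped overlaps (word size 36,
  overlap ≥ 40 nt at ≥ 80% identity), single-linkage clusters with
  majority consensus and cluster/singleton bookkeeping.
- **ORF & secretome calling**: three-frame translation (unidirectional
  libraries), ORF = longest methionine-to-stop segment with the start M
  inside the first 300 residues, a transparent signal-peptide heuristic
  with an evidence-table override, and a keyword cascade assigning H/S/U
  classes and subcategories.
- **Divergence**: best-hit local alignment (BLOSUM62, gap 11/1) of each
  query against a reference proteome, a ≥ 100-aa alignment filter, allele
  dedup at 80% similarity, class-mean percent identity and a Mann-Whitney
  rank-sum comparison. For a pair of mosquito sialomes this contrast is
  roughly 70% identity (S) versus 91% (H).
- **Codon volatility**: v(c) = the fraction of a codon's nine
  point-mutation neighbors (stop neighbors excluded) encoding a different
  amino acid; per-gene means, per-class mean ± SE, Welch t test.
- **Cross-library abundance**: pooled-rate expected counts and chi-square
  homogeneity tests (contingency and class-only modes).
- **Phylogenies**: p/Poisson protein distances, a deterministic
  neighbor-joining implementation (exact on additive matrices), and
  column-resampling bootstrap supports written into Newick node labels.
- **Synthetic data**: generators for EST libraries with Zipf-skewed
  abundance, ortholog pairs at target identity, coding genes at target
  volatility, and protein families with known trees — every downstream
  stage is testable against ground truth.

## Worked example

```r
library(sialome)

# a small synthetic EST library, clustered with the classic thresholds
sim <- simulate_transcriptome_and_reads(synthetic_config(
  seed = 42, n_transcripts = 40, n_reads = 150, transcript_length = 500,
  read_length_mean = 200, read_length_sd = 20, error_rate = 0.01))
cluster_reads(sim$reads)
#> EST clustering: 150 reads in 32 clusters (14 singletons)
```

Only 32 of the 40 transcripts were hit by reads, and 14 clusters are
singletons — the skewed-abundance sampling that makes real EST libraries
singleton-heavy.

```r
# apyrase transcript scarcity across four mosquito salivary libraries
ap <- data.frame(
  library = c("Cquinquefasciatus", "Agambiae", "Aaegypti", "Ctarsalis"),
  observed = c(1, 99, 66, 0), total = c(503, 4066, 4232, 1753))
pooled_expected(ap)[, c("library", "observed", "total", "expected")]
#>             library observed total expected
#> 1 Cquinquefasciatus        1   503     7.91
#> 2          Agambiae       99  4066    63.95
#> 3          Aaegypti       66  4232    66.56
#> 4         Ctarsalis        0  1753    27.57
chi <- chi_square_gof(ap)
#> chi-square = 53.67, df = 3, P = 1.3e-11
```

Under a common pooled rate the two *Culex* libraries should have shown
about 8 and 28 apyrase ESTs; they show 1 and 0. The chi-square in the low
50s (P << 0.001) confirms apyrase transcripts are genuinely depleted in
*Culex* saliva, consistent with bird-feeding hosts lacking platelets.

```r
# codon volatility class contrast on genes with tuned codon usage
gh <- simulate_coding_genes(205, codon_usage_for_volatility(0.761), 400,
                            seed = 1, prefix = "H")
gs <- simulate_coding_genes(80, codon_usage_for_volatility(0.775), 400,
                            seed = 2, prefix = "S")
vol <- compare_class_volatility(c(gh$seq, gs$seq),
                                c(rep("H", 205), rep("S", 80)))
vol$summary
#>   class   n   mean        se
#> 1     H 205 0.7617 0.0004998
#> 2     S  80 0.7750 0.0006949
#> Welch t = -15.56, P = 3.5e-34
```

The recovered class means sit within 0.001 of the configured targets, and
the class separation is overwhelming at these sample sizes: a point
mutation in a secreted-class gene is measurably more likely to change the
protein.

See `vignettes/sialome-methods.Rmd` for the models, parameter defaults,
and the design decisions behind each stage.

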