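# Independent oracles, deliberately implemented without reference to the
# package's own code paths.

# Codon volatility by direct enumeration, translating with seqinr (an
# implementation of the standard code independent of Biostrings).
oracle_volatility <- function(codon) {
  tr <- function(cod) seqinr::translate(strsplit(cod, "")[[1L]])
  aa <- tr(codon)
  stopifnot(aa != "*")
  nb <- character(0)
  for (pos in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
      x <- codon
      substr(x, pos, pos) <- b
      nb <- c(nb, x)
    }
  }
  nb_aa <- vapply(nb, tr, character(1))
  nb_aa <- nb_aa[nb_aa != "*"]
  sum(nb_aa != aa) / length(nb_aa)
}

# Exhaustive affine-gap global alignment score by path enumeration
# (no memoization; only usable for very short sequences).
oracle_global_score <- function(a, b, mat, gap_open, gap_extend) {
  ca <- strsplit(a, "")[[1L]]
  cb <- strsplit(b, "")[[1L]]
  rec <- function(i, j, last) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      best <- max(best, mat[ca[i], cb[j]] + rec(i + 1L, j + 1L, "M"))
    }
    if (i <= length(ca)) {
      cost <- if (last == "D") gap_extend else gap_open + gap_extend
      best <- max(best, -cost + rec(i + 1L, j, "D"))
    }
    if (j <= length(cb)) {
      cost <- if (last == "I") gap_extend else gap_open + gap_extend
      best <- max(best, -cost + rec(i, j + 1L, "I"))
    }
    best
  }
  rec(1L, 1L, "S")
}

# Local score = best global score over all substring pairs, or 0.
oracle_local_score <- function(a, b, mat, gap_open, gap_extend) {
  best <- 0
  for (i1 in seq_len(nchar(a))) for (i2 in i1:nchar(a)) {
    for (j1 in seq_len(nchar(b))) for (j2 in j1:nchar(b)) {
      best <- max(best, oracle_global_score(
        substr(a, i1, i2), substr(b, j1, j2), mat, gap_open, gap_extend))
    }
  }
  best
}

# Exact two-sided Mann-Whitney P by enumeration of rank assignments.
oracle_mw_exact_p <- function(x, y) {
  m <- length(x)
  n <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  sets <- utils::combn(m + n, m)
  ranks <- rank(pooled)
  us <- apply(sets, 2L, function(id) sum(ranks[id]) - m * (m + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Random additive distance matrix with its generating tree.
random_additive <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, tip.label = sprintf("T%02d", seq_len(n_taxa)))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  d <- cophenetic(tr)
  d <- d[order(rownames(d)), order(colnames(d))]
  list(tree = tr, d = d)
}

# Reads of a transcript laid end to end with a fixed step, so every
# adjacent pair overlaps by (read_len - step) nt exactly.
tile_reads <- function(transcript, read_len, step, prefix) {
  starts <- seq(1L, max(1L, nchar(transcript) - read_len + 1L), by = step)
  data.frame(
    id = sprintf("%s_%02d", prefix, seq_along(starts)),
    seq = substring(transcript, starts, pmin(starts + read_len - 1L,
                                             nchar(transcript))),
    stringsAsFactors = FALSE
  )
}

# Components of the positional-overlap graph from a simulation truth map:
# reads of one transcript are linked iff their coordinates overlap by at
# least min_overlap nt. On error-free libraries this is exactly what the
# word-seeded overlap clustering should recover.
truth_components <- function(truth, min_overlap = 40L) {
  n <- nrow(truth)
  parent <- seq_len(n)
  findp <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (truth$transcript_id[i] == truth$transcript_id[j]) {
      ov <- min(truth$end[i], truth$end[j]) -
        max(truth$start[i], truth$start[j]) + 1L
      if (ov >= min_overlap) {
        pi <- findp(i); pj <- findp(j)
        if (pi != pj) parent[max(pi, pj)] <- min(pi, pj)
      }
    }
  }
  split(truth$read_id, vapply(seq_len(n), findp, integer(1)))
}

canonical_partition <- function(part) {
  unname(sort(vapply(part, function(g) paste(sort(g), collapse = ","),
                     character(1))))
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
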