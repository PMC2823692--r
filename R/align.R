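#' Protein alignment scoring scheme
#'
#' BLOSUM62 with affine gap penalties of -11 (open) and -1 (extend) — the
#' blastp defaults. \code{X} is treated as missing data: it scores 0 against
#' every residue and never counts as an identity or a positive.
#'
#' @param matrix_name Substitution matrix name (only shipped matrix:
#'   \code{"BLOSUM62"}).
#' @param gap_open,gap_extend Positive penalties (costs) for opening and
#'   extending a gap.
#' @return A list with the substitution matrix and gap costs.
#' @export
scoring_scheme <- function(matrix_name = "BLOSUM62", gap_open = 11,
                           gap_extend = 1) {
  if (gap_open <= 0 || gap_extend <= 0) stop("gap costs must be positive")
  e <- new.env()
  utils::data(list = matrix_name, package = "Biostrings", envir = e)
  mat <- get(matrix_name, envir = e)
  mat["X", ] <- 0
  mat[, "X"] <- 0
  list(matrix = mat, gap_open = gap_open, gap_extend = gap_extend,
       name = matrix_name)
}

#' Optimal pairwise protein alignment with identity statistics
#'
#' Affine-gap dynamic-programming alignment (local Smith-Waterman by
#' default, mirroring blastp's reporting of its best HSP; global
#' Needleman-Wunsch available). Statistics are computed over the aligned
#' columns: identities are exact residue matches, similarities are pairs
#' with a positive substitution score, and both fractions use the full
#' alignment length including gap columns.
#'
#' @param a,b Protein sequences (20-letter alphabet plus X).
#' @param scheme From [scoring_scheme()].
#' @param mode \code{"local"} or \code{"global"}.
#' @return A list with \code{score}, \code{aligned_a}, \code{aligned_b},
#'   \code{columns}, \code{identities}, \code{similarities},
#'   \code{percent_identity} and \code{percent_similarity} (fractions).
#' @export
align_proteins <- function(a, b, scheme = scoring_scheme(),
                           mode = c("local", "global")) {
  mode <- match.arg(mode)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = mode, substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend
  )
  pa <- as.character(Biostrings::pattern(aln))
  pb <- as.character(Biostrings::subject(aln))
  alignment_stats(pa, pb, scheme, score = BiocGenerics::score(aln))
}

# identity/similarity bookkeeping over two aligned (gapped) strings
alignment_stats <- function(pa, pb, scheme, score = NA_real_) {
  ca <- strsplit(pa, "")[[1L]]
  cb <- strsplit(pb, "")[[1L]]
  cols <- length(ca)
  resid <- ca != "-" & cb != "-"
  ident <- sum(resid & ca == cb & ca != "X")
  simil <- sum(vapply(which(resid), function(i) {
    scheme$matrix[ca[i], cb[i]] > 0
  }, logical(1)))
  list(score = score, aligned_a = pa, aligned_b = pb, columns = cols,
       identities = ident, similarities = simil,
       percent_identity = ident / cols,
       percent_similarity = simil / cols)
}

#' Remove putative alleles and near-identical duplicates
#'
#' Within one set (typically all sequences of a class from one species),
#' repeatedly drops the smaller member of any pair whose alignment
#' similarity reaches the threshold — the conventional guard against
#' counting alleles or recent duplications as independent data points.
#' Similarity is blast-style positives from the best local alignment,
#' taken relative to the length of the shorter sequence: anchoring the
#' denominator to the sequence (not to the aligned columns alone) keeps
#' short high-scoring local segments between unrelated proteins from
#' triggering the rule. Pairs are visited in descending length order; when
#' lengths tie the lexicographically larger id is dropped, making the
#' result independent of the input order.
#'
#' @param seqs Named character vector of protein sequences (names = ids).
#' @param scheme From [scoring_scheme()].
#' @param dedup_similarity Similarity threshold (default 0.80).
#' @param use_identity Use percent identity instead of blast-style
#'   positives for the threshold.
#' @return The retained subset of \code{seqs} (named, original order).
#' @export
dedup_alleles <- function(seqs, scheme = scoring_scheme(),
                          dedup_similarity = 0.80, use_identity = FALSE) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  ord <- order(-nchar(seqs), names(seqs))
  keep <- rep(TRUE, length(seqs))
  for (i in seq_along(ord)) {
    if (!keep[ord[i]]) next
    for (j in seq_along(ord)) {
      if (j <= i || !keep[ord[j]]) next
      st <- align_proteins(seqs[[ord[i]]], seqs[[ord[j]]], scheme, "local")
      shorter <- min(nchar(seqs[[ord[i]]]), nchar(seqs[[ord[j]]]))
      sim <- (if (use_identity) st$identities else st$similarities) / shorter
      if (sim >= dedup_similarity) keep[ord[j]] <- FALSE
    }
  }
  seqs[keep]
}

#' Cross-species class identity comparison
#'
#' For every query protein, finds the best-scoring local alignment against a
#' reference proteome, keeps queries whose best alignment spans at least
#' \code{min_alignment_length} residues, averages percent identity per
#' class, and compares the two class identity samples with a two-sided
#' Mann-Whitney rank-sum test. Best hit means highest raw alignment score,
#' as a blast search would rank it, not highest identity.
#'
#' @param queries Named character vector of query proteins.
#' @param class Character vector of class labels parallel to
#'   \code{queries}; exactly two distinct labels.
#' @param reference Named character vector of reference proteins.
#' @param scheme From [scoring_scheme()].
#' @param min_alignment_length Minimum aligned columns for a query to enter
#'   the class mean (default 100 aa).
#' @return A list with \code{per_query} (best hit, aligned length, percent
#'   identity/similarity, kept flag), \code{summary} (per-class n and mean
#'   identity over kept queries), \code{U} and \code{p_value}.
#' @export
class_identity <- function(queries, class, reference,
                           scheme = scoring_scheme(),
                           min_alignment_length = 100L) {
  stopifnot(length(queries) == length(class), length(reference) >= 1L)
  cls <- sort(unique(class))
  if (length(cls) != 2L) stop("exactly two classes required")
  per_query <- do.call(rbind, lapply(seq_along(queries), function(i) {
    alns <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(rep(queries[[i]], length(reference))),
      Biostrings::AAStringSet(reference),
      type = "local", substitutionMatrix = scheme$matrix,
      gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend
    )
    best <- which.max(BiocGenerics::score(alns))
    st <- alignment_stats(
      as.character(Biostrings::pattern(alns[best])),
      as.character(Biostrings::subject(alns[best])),
      scheme, score = BiocGenerics::score(alns)[best])
    data.frame(
      query = names(queries)[i], class = class[i],
      best_hit = names(reference)[best], score = st$score,
      aligned_length = st$columns,
      percent_identity = st$percent_identity,
      percent_similarity = st$percent_similarity,
      kept = st$columns >= min_alignment_length,
      stringsAsFactors = FALSE
    )
  }))
  kept <- per_query[per_query$kept, ]
  n <- table(factor(kept$class, levels = cls))
  if (any(n == 0L)) {
    stop("class '", cls[n == 0L][1L],
         "' has no queries surviving the alignment-length filter")
  }
  mu <- tapply(kept$percent_identity, factor(kept$class, levels = cls), mean)
  mw <- mann_whitney(kept$percent_identity[kept$class == cls[1L]],
                     kept$percent_identity[kept$class == cls[2L]])
  list(
    per_query = per_query,
    summary = data.frame(class = cls, n = as.integer(n),
                         mean_identity = as.numeric(mu),
                         stringsAsFactors = FALSE),
    U = mw$U, p_value = mw$p_value
  )
}

#' Mann-Whitney rank-sum test
#'
#' Two-sided Mann-Whitney U. The P value is exact (by enumeration of rank
#' assignments) when the combined sample size is at most 12 and there are no
#' ties; otherwise the normal approximation with tie correction and
#' continuity correction is used. U is reported for the first sample, so
#' swapping the samples maps U to n1*n2 - U with the same P.
#'
#' @param x,y Numeric samples, both non-empty.
#' @return A list with \code{U}, \code{p_value}, \code{method}
#'   (\code{"exact"} or \code{"normal"}) and \code{degenerate} (TRUE when
#'   every value in both samples is identical, in which case P = 1).
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact P = 0.1
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (length(unique(c(x, y))) == 1L) {
    return(list(U = length(x) * length(y) / 2, p_value = 1,
                method = "degenerate", degenerate = TRUE))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- (length(x) + length(y) <= 12L) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)
  )
  list(U = unname(wt$statistic), p_value = wt$p.value,
       method = if (use_exact) "exact" else "normal", degenerate = FALSE)
}
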