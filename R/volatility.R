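#' The standard genetic code
#'
#' @return A named character vector mapping the 64 codons to one-letter amino
#'   acids, with stop codons mapped to \code{"*"}.
#' @export
standard_genetic_code <- function() {
  Biostrings::GENETIC_CODE
}

#' Codon volatility of a single codon
#'
#' The volatility of a sense codon is the proportion of its single-nucleotide
#' point-mutation neighbors that encode a different amino acid. Each codon
#' has nine such neighbors (three positions times three alternative bases);
#' by default neighbors that are stop codons are removed from the
#' denominator, so denominators are 7, 8 or 9 depending on the codon.
#'
#' @param codon A three-letter codon over \code{A,C,G,T}. Must be a sense
#'   codon: volatility is undefined for stops.
#' @param code Genetic code, as returned by [standard_genetic_code()].
#' @param count_stop_neighbors If \code{TRUE}, stop-codon neighbors stay in
#'   the denominator (and count as "different"); kept for sensitivity
#'   analysis, off by default.
#' @return Volatility as a fraction in (0, 1].
#' @examples
#' codon_volatility("TGG")  # tryptophan: 1.0
#' codon_volatility("GGG")  # glycine: 6/9
#' @export
codon_volatility <- function(codon, code = standard_genetic_code(),
                             count_stop_neighbors = FALSE) {
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon)) stop("not a valid codon: ", codon)
  aa <- code[[codon]]
  if (aa == "*") stop("volatility undefined for stop codon ", codon)
  bases <- c("A", "C", "G", "T")
  nb <- character(0)
  for (pos in 1:3) {
    for (b in setdiff(bases, substr(codon, pos, pos))) {
      x <- codon
      substr(x, pos, pos) <- b
      nb <- c(nb, x)
    }
  }
  nb_aa <- unname(code[nb])
  if (!count_stop_neighbors) nb_aa <- nb_aa[nb_aa != "*"]
  sum(nb_aa != aa) / length(nb_aa)
}

#' Volatility table for all sense codons
#'
#' @inheritParams codon_volatility
#' @return A data frame with columns \code{codon}, \code{aa} and \code{v},
#'   one row per sense codon (61 under the standard code).
#' @export
volatility_table <- function(code = standard_genetic_code(),
                             count_stop_neighbors = FALSE) {
  sense <- names(code)[code != "*"]
  data.frame(
    codon = sense,
    aa = unname(code[sense]),
    v = vapply(sense, codon_volatility, numeric(1), code = code,
               count_stop_neighbors = count_stop_neighbors),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Mean codon volatility of a coding sequence
#'
#' The gene-level volatility is the arithmetic mean of the volatilities of
#' the gene's sense codons. An incomplete trailing codon is trimmed; stop
#' codons and codons containing \code{N} are skipped. The counts of trimmed
#' bases and skipped codons are attached as attributes for QC reporting.
#'
#' @param cds Nucleotide coding sequence (a single string).
#' @inheritParams codon_volatility
#' @return Mean volatility, with attributes \code{n_codons} (usable sense
#'   codons), \code{n_skipped} (stop or N-containing codons) and
#'   \code{n_trimmed} (trailing bases dropped).
#' @export
gene_volatility <- function(cds, code = standard_genetic_code(),
                            count_stop_neighbors = FALSE) {
  cds <- toupper(cds)
  trimmed <- nchar(cds) %% 3L
  n <- nchar(cds) - trimmed
  if (n < 3L) stop("coding sequence shorter than one codon")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  usable <- grepl("^[ACGT]{3}$", codons) &
    standard_or(code, codons) != "*"
  if (!any(usable)) stop("no usable sense codons in sequence")
  tab <- volatility_table(code, count_stop_neighbors)
  v <- mean(tab$v[match(codons[usable], tab$codon)])
  structure(v, n_codons = sum(usable), n_skipped = sum(!usable),
            n_trimmed = trimmed)
}

# vectorised code lookup tolerating non-ACGT codons (which map to NA, then "")
standard_or <- function(code, codons) {
  out <- unname(code[codons])
  out[is.na(out)] <- ""
  out
}

#' Compare mean codon volatility between two gene classes
#'
#' Computes per-gene volatilities, per-class means and standard errors
#' (sample SD over the square root of the number of genes), and a two-sided
#' two-sample t test of the class difference (Welch by default; genes enter
#' unweighted by length).
#'
#' @param cds Character vector of coding sequences.
#' @param class Character vector of class labels, same length as \code{cds};
#'   exactly two distinct labels, each with at least two genes.
#' @param code Genetic code.
#' @param pooled Use the pooled-variance t test instead of Welch.
#' @param count_stop_neighbors Passed to [gene_volatility()].
#' @return A list with \code{per_gene} (data frame of gene volatilities),
#'   \code{summary} (per-class n, mean, se), \code{t}, \code{df} and
#'   \code{p_value}.
#' @export
compare_class_volatility <- function(cds, class,
                                     code = standard_genetic_code(),
                                     pooled = FALSE,
                                     count_stop_neighbors = FALSE) {
  stopifnot(length(cds) == length(class))
  cls <- sort(unique(class))
  if (length(cls) != 2L) stop("exactly two classes required")
  v <- vapply(cds, function(s)
    as.numeric(gene_volatility(s, code, count_stop_neighbors)), numeric(1))
  per_gene <- data.frame(class = class, volatility = unname(v),
                         stringsAsFactors = FALSE)
  n <- tapply(per_gene$volatility, per_gene$class, length)
  if (any(n < 2L)) stop("each class needs at least two genes")
  mu <- tapply(per_gene$volatility, per_gene$class, mean)
  se <- tapply(per_gene$volatility, per_gene$class, stats::sd) / sqrt(n)
  x <- per_gene$volatility[per_gene$class == cls[1L]]
  y <- per_gene$volatility[per_gene$class == cls[2L]]
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    # both classes constant: t.test would refuse; floor the variance
    if (mean(x) == mean(y)) {
      tt <- list(statistic = c(t = 0), parameter = c(df = sum(n) - 2),
                 p.value = 1)
    } else {
      eps <- 1e-24
      tstat <- (mean(x) - mean(y)) / sqrt(eps / length(x) + eps / length(y))
      df <- length(x) + length(y) - 2
      tt <- list(statistic = c(t = tstat), parameter = c(df = df),
                 p.value = 2 * stats::pt(-abs(tstat), df))
    }
  } else {
    tt <- stats::t.test(x, y, var.equal = pooled)
  }
  list(
    per_gene = per_gene,
    summary = data.frame(class = cls, n = as.integer(n[cls]),
                         mean = as.numeric(mu[cls]), se = as.numeric(se[cls]),
                         stringsAsFactors = FALSE),
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value
  )
}
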