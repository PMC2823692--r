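#' Expected class counts under a pooled cross-library rate
#'
#' Given per-library observed counts of a focal transcript class and library
#' totals, estimates the pooled rate p = sum(observed) / sum(total) and the
#' per-library expected counts p * total. The expected counts conserve the
#' observed grand total exactly.
#'
#' @param counts Data frame with columns \code{library}, \code{observed} and
#'   \code{total} (one row per EST library); at least two libraries.
#' @return The input with added columns \code{expected} (unrounded) and
#'   \code{expected_rounded}, plus attribute \code{pooled_rate}.
#' @examples
#' apyrase <- data.frame(
#'   library = c("Cquinq", "Agambiae", "Aaegypti", "Ctarsalis"),
#'   observed = c(1, 99, 66, 0),
#'   total = c(503, 4066, 4232, 1753))
#' pooled_expected(apyrase)
#' @export
pooled_expected <- function(counts) {
  stopifnot(all(c("library", "observed", "total") %in% names(counts)))
  if (nrow(counts) < 2L) stop("need at least two libraries")
  if (any(counts$observed > counts$total)) {
    stop("observed exceeds total for library ",
         counts$library[counts$observed > counts$total][1L])
  }
  tot <- sum(counts$total)
  if (tot == 0) stop("all library totals are zero")
  p <- sum(counts$observed) / tot
  counts$expected <- p * counts$total
  counts$expected_rounded <- round_half_up(counts$expected, 0)
  attr(counts, "pooled_rate") <- p
  counts
}

#' Chi-square test of transcript-class frequency across libraries
#'
#' Tests whether the focal class occurs at the same rate in every library.
#' The default \code{"contingency"} mode builds the 2 x k table of class and
#' non-class counts (df = k - 1, uncorrected Pearson chi-square); the
#' \code{"class_only"} mode sums (O - E)^2 / E over the class cells alone
#' against the pooled-rate expectations. Both modes are reported by
#' abundance summaries because published chi-squares rarely state which cell
#' set was used. Expected cells below 1 set a validity flag rather than
#' refusing the test.
#'
#' @param counts As for [pooled_expected()].
#' @param mode \code{"contingency"} or \code{"class_only"}.
#' @param correct Apply the Yates continuity correction (2 x 2 tables only).
#' @return A list with \code{chi_square}, \code{df}, \code{p_value},
#'   \code{expected} (per-library class expectations), \code{pooled_rate},
#'   \code{mode} and \code{low_expected} (validity flag).
#' @export
chi_square_gof <- function(counts, mode = c("contingency", "class_only"),
                           correct = FALSE) {
  mode <- match.arg(mode)
  counts <- pooled_expected(counts)
  e <- counts$expected
  if (mode == "contingency") {
    tab <- rbind(class = counts$observed,
                 other = counts$total - counts$observed)
    exp_full <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    suppressWarnings(
      ct <- stats::chisq.test(tab, correct = correct)
    )
    chi <- unname(ct$statistic)
    df <- unname(ct$parameter)
    p <- unname(ct$p.value)
    low <- any(exp_full < 1)
  } else {
    chi <- sum((counts$observed - e)^2 / e)
    df <- nrow(counts) - 1L
    p <- stats::pchisq(chi, df, lower.tail = FALSE)
    low <- any(e < 1)
  }
  list(chi_square = chi, df = df, p_value = p,
       expected = stats::setNames(e, counts$library),
       pooled_rate = attr(counts, "pooled_rate"),
       mode = mode, low_expected = low)
}

#' Percent of a group, rounded half-up to one decimal
#'
#' Table-style percentage formatting: 100 * count / group_total with
#' conventional half-up rounding to one decimal place (base \code{round}
#' rounds half to even, which does not reproduce published tables).
#'
#' @param count Member count (vectorised).
#' @param group_total Group size, at least 1.
#' @return Percentages to one decimal.
#' @examples
#' percent_of_group(279, 637)   # 43.8
#' percent_of_group(771, 1753)  # 44.0
#' @export
percent_of_group <- function(count, group_total) {
  stopifnot(all(group_total >= 1), all(count <= group_total), all(count >= 0))
  round_half_up(100 * count / group_total, 1)
}

# round half away from zero, as tables are conventionally formatted
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
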