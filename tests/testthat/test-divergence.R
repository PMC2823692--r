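scheme <- scoring_scheme()

test_that("alignment statistics on constructed pairs", {
  self <- align_proteins("MKTAYIAKQR", "MKTAYIAKQR")
  expect_equal(self$percent_identity, 1.0)
  expect_equal(self$columns, 10L)

  g <- align_proteins("ACDEFGHIKL", "ACDEFGHIKV", mode = "global")
  expect_equal(g$identities, 9L)
  expect_equal(g$percent_identity, 0.9)

  loc <- align_proteins("XXXXMKTXXXX", "MKT")
  expect_equal(loc$columns, 3L)
  expect_equal(loc$percent_identity, 1.0)

  expect_error(align_proteins("", "MKT"), "empty")
})

test_that("alignment scores equal the exhaustive small-case oracle", {
  set.seed(101)
  aas <- c("A", "R", "N", "D", "W")
  for (rep in 1:6) {
    a <- paste(sample(aas, 4, replace = TRUE), collapse = "")
    b <- paste(sample(aas, 4, replace = TRUE), collapse = "")
    g <- align_proteins(a, b, scheme, mode = "global")
    expect_equal(g$score,
                 oracle_global_score(a, b, scheme$matrix,
                                     scheme$gap_open, scheme$gap_extend),
                 info = paste("global", a, b))
    l <- align_proteins(a, b, scheme, mode = "local")
    expect_equal(max(l$score, 0),
                 oracle_local_score(a, b, scheme$matrix,
                                    scheme$gap_open, scheme$gap_extend),
                 info = paste("local", a, b))
  }
})

test_that("percent identity is invariant under sequence swap", {
  a <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  b <- "MKTAYLAKQRQISFVKSAFSRQLEERLGQIEVQ"
  expect_equal(align_proteins(a, b)$percent_identity,
               align_proteins(b, a)$percent_identity)
})

test_that("X residues never count as identities and score zero", {
  st <- align_proteins("MKXAY", "MKXAY", mode = "global")
  expect_equal(st$identities, 4L)  # the X column is excluded
  expect_equal(unname(scheme$matrix["X", "W"]), 0)
})

test_that("allele dedup drops the shorter of similar pairs, order-independently", {
  base <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRVGDGTQDNLSGAEKAVQ"
  shorter <- substr(base, 1, 45)
  unrelated <- "MWWDNCPECGHEYHWDNNCPHHGGEWNCDDHPGECWHY"
  seqs <- c(A = base, B = shorter, C = unrelated)
  kept <- dedup_alleles(seqs)
  expect_setequal(names(kept), c("A", "C"))
  # identical pair: one survivor
  expect_length(dedup_alleles(c(x = base, y = base)), 1L)
  # all pairwise similarities below threshold: all retained
  expect_length(dedup_alleles(c(A = base, C = unrelated)), 2L)
  # input order does not matter
  for (perm in list(c(1, 2, 3), c(3, 2, 1), c(2, 3, 1))) {
    expect_setequal(names(dedup_alleles(seqs[perm])), c("A", "C"))
  }
  # equal lengths: the lexicographically larger id is dropped
  twins <- c(zz = base, aa = base)
  expect_equal(names(dedup_alleles(twins)), "aa")
})

test_that("Mann-Whitney matches the enumeration oracle and is symmetric", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 0.1)
  expect_equal(mw$method, "exact")
  expect_equal(mw$p_value, oracle_mw_exact_p(c(1, 2, 3), c(4, 5, 6)))

  set.seed(7)
  x <- sample(seq(0.1, 9.9, by = 0.1), 5)
  y <- sample(setdiff(seq(0.1, 9.9, by = 0.1), x), 6)
  expect_equal(mann_whitney(x, y)$p_value, oracle_mw_exact_p(x, y))

  # swap symmetry
  a <- mann_whitney(x, y); b <- mann_whitney(y, x)
  expect_equal(a$p_value, b$p_value)
  expect_equal(b$U, length(x) * length(y) - a$U)

  # degenerate samples
  dg <- mann_whitney(rep(2, 4), rep(2, 5))
  expect_equal(dg$p_value, 1)
  expect_true(dg$degenerate)
})

test_that("exact and normal branches agree at the handover where P values matter", {
  # tie-free 6+6 samples spanning U = 0, 4, 8 (exact P from 0.002 to 0.13):
  # across the decision-relevant tail the two branches differ by < 0.01
  # (mid-distribution P values near 0.4 can differ by up to ~0.016)
  for (xidx in list(1:6, c(1, 2, 3, 4, 7, 8), c(1, 2, 3, 4, 9, 10))) {
    pool <- seq(0.5, 6, by = 0.5)
    x <- pool[xidx]
    y <- pool[setdiff(1:12, xidx)]
    mw <- mann_whitney(x, y)
    expect_equal(mw$method, "exact")
    expect_lte(mw$p_value, 0.2)
    approx_p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(mw$p_value - approx_p), 0.01)
  }
})

test_that("class identity keeps only long alignments and recovers truth", {
  # queries identical to references: class means exactly 1
  set.seed(11)
  mk <- function(n, len) {
    vapply(seq_len(n), function(i)
      paste(c("M", sample(rownames(scheme$matrix)[1:20], len - 1, TRUE)),
            collapse = ""), character(1))
  }
  ref <- stats::setNames(mk(6, 120), sprintf("R%d", 1:6))
  out <- class_identity(stats::setNames(ref, sprintf("Q%d", 1:6)),
                        rep(c("H", "S"), each = 3), ref)
  expect_equal(out$summary$mean_identity, c(1, 1))

  # a query whose best alignment is under 100 aa is filtered out
  short_q <- c(Qs = substr(ref[[1]], 1, 99))
  mixed <- class_identity(
    c(stats::setNames(ref, sprintf("Q%d", 1:6)), short_q),
    c(rep(c("H", "S"), each = 3), "S"), ref)
  expect_false(mixed$per_query$kept[mixed$per_query$query == "Qs"])
  expect_equal(mixed$summary$n, c(3L, 3L))

  # every query filtered from one class: explanatory refusal
  expect_error(
    class_identity(c(short_q, stats::setNames(ref[1:2], c("Qa", "Qb"))),
                   c("S", "H", "H"), ref),
    "alignment-length filter")
})

test_that("identity estimates on simulated ortholog pairs are unbiased", {
  pairs <- simulate_ortholog_pairs(40, 0.85, identity_sd = 0,
                                   length = 400, seed = 21)
  expect_equal(mean(pairs$true_identity), 0.85,
               tolerance = 2 * sqrt(0.85 * 0.15 / 400 / 40) + 1e-3)
  out <- class_identity(
    c(pairs$a[1:20], pairs$a[21:40]),
    rep(c("g1", "g2"), each = 20),
    pairs$b)
  expect_equal(out$summary$mean_identity,
               c(mean(pairs$true_identity[1:20]),
                 mean(pairs$true_identity[21:40])),
               tolerance = 0.01)
})
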