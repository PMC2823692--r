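test_that("protein distances follow the closed forms with pairwise deletion", {
  al <- c(s1 = "AAAA", s2 = "AAAT")
  p <- protein_distance(al, "p_distance")
  expect_equal(p["s1", "s2"], 0.25)
  ps <- protein_distance(al, "poisson")
  expect_equal(ps["s1", "s2"], -log(0.75))

  same <- protein_distance(c(a = "MKTA", b = "MKTA"))
  expect_true(all(same == 0))

  # gap/X columns excluded per pair
  gx <- protein_distance(c(a = "MK-A", b = "MKXA", c = "MKTT"))
  expect_equal(gx["a", "b"], 0)      # only M,K,A comparable... M,K,A -> 2 cols
  expect_equal(gx["a", "c"], 1 / 3)

  expect_error(protein_distance(c(a = "WWWW", b = "MMMM"), "poisson"),
               "infinite")
  expect_error(protein_distance(c(a = "--X-", b = "MKTA")), "comparable")
})

test_that("distance matrices are symmetric and row-order invariant", {
  fam <- simulate_protein_family(90, 5, 0.5, seed = 31)
  d1 <- protein_distance(fam$proteins)
  d2 <- protein_distance(fam$proteins[c(3, 1, 5, 2, 4)])
  expect_equal(d1, t(d1))
  expect_equal(d2[rownames(d1), colnames(d1)], d1)
})

test_that("NJ recovers the worked additive example exactly", {
  d <- matrix(c(0, 3, 8, 9,
                3, 0, 9, 10,
                8, 9, 0, 9,
                9, 10, 9, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(d)
  expect_equal(cophenetic(tr)[rownames(d), colnames(d)], d)
  # branch lengths: A:1, B:2 joined, internal 3, C:4, D:5
  lens <- sort(tr$edge.length)
  expect_equal(lens, c(1, 2, 3, 4, 5))
})

test_that("three taxa resolve by the closed three-point formulas", {
  d <- matrix(c(0, 5, 9, 5, 0, 8, 9, 8, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- nj_tree(d)
  expect_equal(cophenetic(tr)[rownames(d), colnames(d)], d)
  # (dxy+dxz-dyz)/2 = 3, (dxy+dyz-dxz)/2 = 2, (dxz+dyz-dxy)/2 = 6
  expect_equal(sort(tr$edge.length), c(2, 3, 6))
})

test_that("NJ is exact on random additive matrices up to 12 taxa", {
  for (n in c(5, 8, 12)) {
    ra <- random_additive(n, seed = 100 + n)
    tr <- nj_tree(ra$d)
    expect_equal(cophenetic(tr)[rownames(ra$d), colnames(ra$d)], ra$d,
                 tolerance = 1e-9)
    expect_equal(ape::dist.topo(tr, ape::unroot(ra$tree)),
                 structure(0, names = "PH85"), ignore_attr = TRUE)
  }
})

test_that("NJ agrees with an independent implementation on noisy matrices", {
  for (s in 1:3) {
    ra <- random_additive(7, seed = 200 + s)
    set.seed(300 + s)
    noisy <- ra$d + matrix(stats::runif(49, 0, 0.02), 7, 7)
    noisy <- (noisy + t(noisy)) / 2
    diag(noisy) <- 0
    mine <- nj_tree(noisy)
    theirs <- ape::nj(as.dist(noisy))
    expect_equal(ape::dist.topo(mine, theirs),
                 structure(0, names = "PH85"), ignore_attr = TRUE)
  }
})

test_that("NJ matches the all-topology least-squares oracle at 6 taxa", {
  skip_if_not_installed("phangorn")
  ra <- random_additive(6, seed = 401)
  tr <- nj_tree(ra$d)
  topos <- phangorn::allTrees(6, rooted = FALSE,
                              tip.label = rownames(ra$d))
  rss <- vapply(topos, function(tp) {
    fit <- phangorn::nnls.tree(ra$d, tp, method = "unrooted")
    sum((cophenetic(fit)[rownames(ra$d), colnames(ra$d)] - ra$d)^2)
  }, numeric(1))
  best <- topos[[which.min(rss)]]
  expect_lt(min(rss), 1e-12)
  expect_equal(ape::dist.topo(tr, best), structure(0, names = "PH85"),
               ignore_attr = TRUE)
})

test_that("ties and repeated runs give byte-identical trees", {
  # ultrametric equidistant 4-taxon matrix: every Q entry ties
  d <- matrix(2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  t1 <- write_newick(nj_tree(d))
  t2 <- write_newick(nj_tree(d))
  expect_identical(t1, t2)
})

test_that("negative branch estimates are clamped and counted", {
  d <- matrix(c(0, 1, 6, 1, 0, 2, 6, 2, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  # violates the triangle structure enough to force a negative estimate
  tr <- nj_tree(d)
  expect_true(all(tr$edge.length >= 0))
  expect_gte(attr(tr, "clamped"), 1L)
})

test_that("bootstrap supports behave under resampling invariance and seeds", {
  # two clearly distinct groups with zero within-group variation:
  # every column supports the same split, so its support is 100
  al <- c(g1a = strrep("A", 30), g1b = strrep("A", 30),
          g2a = strrep("W", 30), g2b = strrep("W", 30))
  al <- vapply(seq_along(al), function(i)
    paste0(al[i], c("MK", "MK", "MR", "MR")[i]), character(1))
  names(al) <- c("g1a", "g1b", "g2a", "g2b")
  bt <- bootstrap_support(al, n_replicates = 50, seed = 42)
  sup <- suppressWarnings(as.integer(bt$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))

  one <- bootstrap_support(al, n_replicates = 1, seed = 7)
  s1 <- suppressWarnings(as.integer(one$node.label))
  expect_true(all(s1[!is.na(s1)] %in% c(0, 100)))

  fam <- simulate_protein_family(60, 5, 0.6, seed = 77)
  b1 <- bootstrap_support(fam$proteins, n_replicates = 60, seed = 5)
  b2 <- bootstrap_support(fam$proteins, n_replicates = 60, seed = 5)
  expect_identical(write_newick(b1), write_newick(b2))
})

test_that("bipartition supports are invariant to leaf permutation of the input", {
  fam <- simulate_protein_family(80, 6, 0.5, seed = 88)
  al <- fam$proteins
  b1 <- bootstrap_support(al, n_replicates = 40, seed = 9)
  b2 <- bootstrap_support(al[c(4, 2, 6, 1, 5, 3)], n_replicates = 40,
                          seed = 9)
  key <- function(tree) {
    sup <- tree$node.label[tree$node.label != ""]
    sort(as.integer(sup))
  }
  expect_identical(key(b1), key(b2))
})
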