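AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Default configuration for the synthetic EST study
#'
#' Bundles the generator parameters emulating a single-pass Sanger EST
#' study of a mosquito salivary-gland library: 1,753 reads drawn from a
#' Zipf-skewed transcript pool (few dominant secreted families, many
#' singletons), ortholog pairs at the two divergence regimes typical of
#' secreted (~70% identity) versus housekeeping (~91%) proteins, coding
#' genes whose codon usage is tuned to class-mean volatilities near 0.761
#' and 0.775, and a small paralog family for tree building.
#'
#' @param seed Integer seed recorded in every output.
#' @param ... Overrides for any listed field.
#' @return A validated list of generator parameters.
#' @export
synthetic_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_transcripts = 1200L,
    transcript_length = 900L,
    abundance_alpha = 1.0,
    n_reads = 1753L,
    read_length_mean = 500,
    read_length_sd = 80,
    error_rate = 0.01,
    indel_rate = 0,
    n_pairs_H = 169L,
    n_pairs_S = 50L,
    target_identity_H = 0.912,
    target_identity_S = 0.701,
    identity_sd = 0.05,
    ortholog_length = 300L,
    volatility_H = 0.761,
    volatility_S = 0.775,
    n_genes_H = 205L,
    n_genes_S = 80L,
    n_codons = 400L,
    family_size = 8L,
    family_divergence = 0.5
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field: ", bad[1L])
  cfg[names(over)] <- over
  stopifnot(cfg$n_transcripts >= 1L, cfg$abundance_alpha > 0,
            cfg$error_rate >= 0, cfg$error_rate <= 1,
            cfg$target_identity_H > 0, cfg$target_identity_H <= 1,
            cfg$target_identity_S > 0, cfg$target_identity_S <= 1)
  cfg
}

random_cds_transcript <- function(total_length, usage) {
  utr5 <- 50L
  n_codons <- max(10L, (total_length - utr5 - 6L - 50L) %/% 3L)
  cds <- paste0("ATG",
                paste(sample(names(usage), n_codons, TRUE, usage),
                      collapse = ""),
                "TAA")
  utr3 <- total_length - utr5 - nchar(cds)
  paste0(rand_nt(utr5), cds, if (utr3 > 0) rand_nt(utr3) else "")
}

rand_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a transcript pool and an EST library sampled from it
#'
#' Transcripts are random CDS-containing sequences. Read abundance follows
#' a normalized power law p_i proportional to i^(-alpha), reproducing the
#' singleton-heavy cluster spectrum of real EST libraries. Reads are
#' forward-strand subsequences with uniform start, normal length, and
#' i.i.d. substitution errors; a read longer than its transcript is
#' truncated to the transcript. The complete read-to-transcript truth map
#' (with positions) is returned beside the data.
#'
#' @param config From [synthetic_config()].
#' @return A list with \code{transcripts} (data frame id/seq), \code{reads}
#'   (data frame id/seq) and \code{truth} (read_id, transcript_id, start,
#'   end, 1-based transcript coordinates).
#' @export
simulate_transcriptome_and_reads <- function(config = synthetic_config()) {
  set.seed(config$seed)
  usage <- stats::setNames(
    rep(1 / 61, 61),
    names(standard_genetic_code())[standard_genetic_code() != "*"])
  transcripts <- data.frame(
    id = sprintf("TR%05d", seq_len(config$n_transcripts)),
    seq = vapply(seq_len(config$n_transcripts), function(i)
      random_cds_transcript(config$transcript_length, usage), character(1)),
    stringsAsFactors = FALSE
  )
  p <- seq_len(config$n_transcripts)^(-config$abundance_alpha)
  p <- p / sum(p)
  pick <- sample.int(config$n_transcripts, config$n_reads, TRUE, p)
  lens <- pmax(50L, round(stats::rnorm(config$n_reads,
                                       config$read_length_mean,
                                       config$read_length_sd)))
  reads <- vector("list", config$n_reads)
  truth <- vector("list", config$n_reads)
  for (r in seq_len(config$n_reads)) {
    tr <- transcripts$seq[pick[r]]
    len <- min(lens[r], nchar(tr))
    start <- sample.int(nchar(tr) - len + 1L, 1L)
    s <- substr(tr, start, start + len - 1L)
    if (config$error_rate > 0) {
      ch <- strsplit(s, "")[[1L]]
      err <- stats::runif(len) < config$error_rate
      if (any(err)) {
        ch[err] <- vapply(ch[err], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
        s <- paste(ch, collapse = "")
      }
    }
    reads[[r]] <- s
    truth[[r]] <- c(pick[r], start, start + len - 1L)
  }
  tm <- do.call(rbind, truth)
  list(
    transcripts = transcripts,
    reads = data.frame(id = sprintf("EST%05d", seq_len(config$n_reads)),
                       seq = unlist(reads), stringsAsFactors = FALSE),
    truth = data.frame(read_id = sprintf("EST%05d", seq_len(config$n_reads)),
                       transcript_id = transcripts$id[tm[, 1L]],
                       start = tm[, 2L], end = tm[, 3L],
                       stringsAsFactors = FALSE)
  )
}

#' Simulate ortholog protein pairs at a target identity
#'
#' Each pair starts from a random protein A; B substitutes every site
#' independently with probability 1 - p, where p is drawn per pair from a
#' normal(target_identity, identity_sd) truncated to (0, 1]. Substitutions
#' are uniform over the 19 alternative residues, so the realized identity
#' (recorded exactly as the fraction of unchanged sites) concentrates
#' binomially around p.
#'
#' @param n Number of pairs (>= 1).
#' @param target_identity Target fraction of identical sites, in (0, 1].
#' @param identity_sd Between-pair standard deviation of the identity.
#' @param length Protein length in residues.
#' @param seed Integer seed.
#' @param prefix Id prefix for the pair names.
#' @return A list with named vectors \code{a} and \code{b} and numeric
#'   \code{true_identity}.
#' @export
simulate_ortholog_pairs <- function(n, target_identity, identity_sd = 0.05,
                                    length = 300L, seed = 1L,
                                    prefix = "P") {
  if (n <= 0) stop("n must be positive")
  if (target_identity <= 0 || target_identity > 1) {
    stop("target_identity must be in (0, 1]")
  }
  set.seed(seed)
  a <- b <- character(n)
  tid <- numeric(n)
  for (i in seq_len(n)) {
    p <- Inf
    while (p <= 0 || p > 1) {
      p <- stats::rnorm(1L, target_identity, identity_sd)
      if (identity_sd == 0) p <- target_identity
    }
    sa <- c("M", sample(AA20, length - 1L, replace = TRUE))
    sub <- stats::runif(length) < (1 - p)
    sub[1L] <- FALSE  # keep the initiator methionine comparable
    sb <- sa
    if (any(sub)) {
      sb[sub] <- vapply(sa[sub], function(r)
        sample(setdiff(AA20, r), 1L), character(1))
    }
    a[i] <- paste(sa, collapse = "")
    b[i] <- paste(sb, collapse = "")
    tid[i] <- mean(sa == sb)
  }
  list(a = stats::setNames(a, sprintf("%s%03d_A", prefix, seq_len(n))),
       b = stats::setNames(b, sprintf("%s%03d_B", prefix, seq_len(n))),
       true_identity = tid)
}

#' Simulate coding genes under a fixed codon usage
#'
#' Each gene is an initiator ATG, \code{n_codons} i.i.d. draws from the
#' usage distribution over the 61 sense codons, and one stop. The expected
#' per-gene volatility is (up to the single initiator codon) the
#' usage-weighted mean of the codon volatility table, which is what lets
#' tests construct gene classes with a known mean volatility.
#'
#' @param n Number of genes.
#' @param codon_usage Named numeric vector over the 61 sense codons,
#'   summing to 1; any mass on a stop codon is an error.
#' @param n_codons Codons drawn per gene (besides start and stop).
#' @param seed Integer seed.
#' @param prefix Id prefix.
#' @return A data frame with columns \code{id} and \code{seq}.
#' @export
simulate_coding_genes <- function(n, codon_usage, n_codons = 400L,
                                  seed = 1L, prefix = "G") {
  code <- standard_genetic_code()
  codon_usage <- codon_usage[codon_usage > 0]
  if (any(code[names(codon_usage)] == "*")) {
    stop("codon usage assigns mass to stop codons")
  }
  if (abs(sum(codon_usage) - 1) > 1e-9) stop("codon usage must sum to 1")
  set.seed(seed)
  data.frame(
    id = sprintf("%s%04d", prefix, seq_len(n)),
    seq = vapply(seq_len(n), function(i) {
      paste0("ATG", paste(sample(names(codon_usage), n_codons, TRUE,
                                 codon_usage), collapse = ""), "TAA")
    }, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Codon usage with a prescribed mean volatility
#'
#' Blends the uniform usage over the 61 sense codons with a point mass on
#' an extreme-volatility codon (TGG at 1.0, or the least volatile codon)
#' so that the usage-weighted mean volatility equals \code{target}.
#'
#' @param target Desired usage-weighted mean volatility.
#' @return A named usage vector over the 61 sense codons.
#' @export
codon_usage_for_volatility <- function(target) {
  tab <- volatility_table()
  uniform <- stats::setNames(rep(1 / nrow(tab), nrow(tab)), tab$codon)
  m0 <- mean(tab$v)
  if (abs(target - m0) < 1e-12) return(uniform)
  extreme <- if (target > m0) tab$codon[which.max(tab$v)] else
    tab$codon[which.min(tab$v)]
  ve <- tab$v[tab$codon == extreme]
  w <- (target - m0) / (ve - m0)
  if (w < 0 || w > 1) stop("target volatility out of attainable range")
  usage <- (1 - w) * uniform
  usage[extreme] <- usage[extreme] + w
  usage
}

#' Simulate a protein family down a random tree
#'
#' Draws a random binary topology with branch lengths rescaled so the mean
#' root-to-tip path equals \code{divergence} (expected substitutions per
#' site), then evolves a random ancestor along each edge by a Poisson
#' number of substitutions (uniform sites, uniform alternative residues).
#'
#' @param ancestor_length Protein length in residues.
#' @param family_size Number of tips (>= 3).
#' @param divergence Mean root-to-tip substitutions per site (>= 0).
#' @param seed Integer seed.
#' @return A list with \code{proteins} (named by tip label) and
#'   \code{tree} (the generating \code{phylo} object).
#' @export
simulate_protein_family <- function(ancestor_length = 200L, family_size = 8L,
                                    divergence = 0.5, seed = 1L) {
  if (family_size < 3L) stop("family_size must be >= 3")
  if (divergence < 0) stop("divergence must be >= 0")
  set.seed(seed)
  tree <- ape::rtree(family_size, tip.label = sprintf("FAM%02d",
                                                      seq_len(family_size)))
  depths <- ape::node.depth.edgelength(tree)[seq_len(family_size)]
  scale <- if (mean(depths) > 0) divergence / mean(depths) else 0
  tree$edge.length <- tree$edge.length * scale
  tree <- stats::reorder(tree, "cladewise")  # edges in preorder
  root <- family_size + 1L
  seqs <- vector("list", max(tree$edge))
  seqs[[root]] <- sample(AA20, ancestor_length, replace = TRUE)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]
    child <- tree$edge[e, 2L]
    s <- seqs[[par]]
    nsub <- stats::rpois(1L, tree$edge.length[e] * ancestor_length)
    if (nsub > 0) {
      sites <- sample.int(ancestor_length, nsub, replace = TRUE)
      for (k in sites) s[k] <- sample(setdiff(AA20, s[k]), 1L)
    }
    seqs[[child]] <- s
  }
  proteins <- vapply(seq_len(family_size), function(i)
    paste(seqs[[i]], collapse = ""), character(1))
  names(proteins) <- tree$tip.label
  list(proteins = proteins, tree = tree)
}
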