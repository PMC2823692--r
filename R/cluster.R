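#' Clustering parameters
#'
#' Defaults follow the classic EST assembly setup: blastn-style exact-word
#' seeding with word size 36 and CAP3-style acceptance of overlaps of at
#' least 40 nt at 80% identity. Note the word size may exceed or undercut
#' the minimum overlap; 36 < 40 is the published combination.
#'
#' @param word_size Exact-word seed length in nt (>= 8).
#' @param min_overlap Minimum accepted overlap length in nt.
#' @param min_identity Minimum identity over the overlapped columns.
#' @return A list of validated parameters.
#' @export
clustering_params <- function(word_size = 36L, min_overlap = 40L,
                              min_identity = 0.80) {
  if (word_size < 8L) stop("word_size must be >= 8")
  if (min_overlap < 1L) stop("min_overlap must be >= 1")
  if (min_identity <= 0 || min_identity > 1) {
    stop("min_identity must be in (0, 1]")
  }
  list(word_size = as.integer(word_size),
       min_overlap = as.integer(min_overlap),
       min_identity = min_identity)
}

kmer_starts <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  stats::setNames(substring(seq, 1:(n - k + 1L), k:n), NULL)
}

#' Best ungapped overlap between two reads
#'
#' Finds the highest-identity dovetail or containment overlap between two
#' reads, seeded by a shared exact word of \code{word_size} nt and extended
#' without gaps. Identity is computed over the overlapped columns, excluding
#' positions where either read has \code{N} (missing data, not mismatch).
#' Forward strand only: the libraries this models are directional.
#'
#' @param a,b Nucleotide sequences (strings over A,C,G,T,N).
#' @param params From [clustering_params()].
#' @return A list with \code{offset} (start of \code{b} relative to
#'   \code{a}, 0-based; negative when \code{b} hangs off the left end),
#'   \code{length} and \code{identity}, or \code{NULL} when no overlap
#'   passes the length and identity thresholds.
#' @export
find_overlap <- function(a, b, params = clustering_params()) {
  k <- params$word_size
  wa <- kmer_starts(a, k)
  wb <- kmer_starts(b, k)
  if (!length(wa) || !length(wb)) return(NULL)
  shared <- intersect(wa[!grepl("N", wa)], wb[!grepl("N", wb)])
  if (!length(shared)) return(NULL)
  offs <- unique(unlist(lapply(shared, function(w) {
    outer(which(wa == w), which(wb == w), "-")
  })))
  la <- nchar(a); lb <- nchar(b)
  best <- NULL
  for (o in sort(offs)) {
    s <- max(1L, 1L + o)          # overlap start, a coordinates
    e <- min(la, lb + o)
    len <- e - s + 1L
    if (len < params$min_overlap) next
    ca <- strsplit(substr(a, s, e), "")[[1L]]
    cb <- strsplit(substr(b, s - o, e - o), "")[[1L]]
    use <- ca != "N" & cb != "N"
    if (!any(use)) next
    ident <- sum(ca[use] == cb[use]) / sum(use)
    if (ident < params$min_identity) next
    if (is.null(best) || ident > best$identity ||
        (ident == best$identity && len > best$length)) {
      best <- list(offset = o, length = len, identity = ident)
    }
  }
  best
}

#' Cluster EST reads by single-linkage over accepted overlaps
#'
#' Builds the graph whose edges are overlaps accepted by [find_overlap()]
#' and reports its connected components: transitive (single-linkage)
#' clustering, the minimal reconstruction of an EST assembly's
#' cluster/singleton bookkeeping. Candidate pairs are restricted to reads
#' sharing at least one exact word, so unrelated reads are never compared.
#'
#' @param reads Data frame with columns \code{id} and \code{seq} (as from
#'   [read_fasta()]); ids must be unique.
#' @param params From [clustering_params()].
#' @return An object of class \code{est_clustering}: a list with
#'   \code{members} (read_id -> cluster_id), \code{clusters} (per-cluster
#'   size, singleton flag and majority consensus), \code{n_clusters} and
#'   \code{n_singletons}. Cluster ids are assigned in order of each
#'   cluster's smallest member id.
#' @export
cluster_reads <- function(reads, params = clustering_params()) {
  stopifnot(all(c("id", "seq") %in% names(reads)))
  if (anyDuplicated(reads$id)) {
    stop("duplicate read id: ", reads$id[duplicated(reads$id)][1L])
  }
  n <- nrow(reads)
  k <- params$word_size
  # word -> reads inverted index
  words <- lapply(reads$seq, function(s) {
    w <- unique(kmer_starts(s, k))
    w[!grepl("N", w)]
  })
  idx <- split(rep(seq_len(n), lengths(words)), unlist(words))
  cand <- unique(do.call(rbind, lapply(idx, function(v) {
    if (length(v) < 2L) return(NULL)
    t(utils::combn(sort(v), 2L))
  })))
  parent <- seq_len(n)
  findp <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  edges <- list()
  if (!is.null(cand)) {
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1L]; j <- cand[r, 2L]
      ov <- find_overlap(reads$seq[i], reads$seq[j], params)
      if (!is.null(ov)) {
        edges[[length(edges) + 1L]] <- list(i = i, j = j,
                                            offset = ov$offset)
        pi <- findp(i); pj <- findp(j)
        if (pi != pj) parent[max(pi, pj)] <- min(pi, pj)
      }
    }
  }
  comp <- vapply(seq_len(n), findp, integer(1))
  groups <- split(seq_len(n), comp)
  # deterministic ids: order components by their smallest member id
  ord <- order(vapply(groups, function(g) min(reads$id[g]), character(1)))
  groups <- groups[ord]
  cluster_ids <- sprintf("CL%04d", seq_along(groups))
  members <- data.frame(
    read_id = reads$id[unlist(groups)],
    cluster_id = rep(cluster_ids, lengths(groups)),
    stringsAsFactors = FALSE
  )
  cons <- vapply(seq_along(groups), function(gi) {
    g <- groups[[gi]]
    consensus(reads$seq[g], reads$id[g],
              Filter(function(e) e$i %in% g, edges), g)
  }, character(1))
  clusters <- data.frame(
    cluster_id = cluster_ids,
    n_members = lengths(groups),
    is_singleton = lengths(groups) == 1L,
    consensus = cons,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(members = members, clusters = clusters,
                 n_clusters = nrow(clusters),
                 n_singletons = sum(clusters$is_singleton),
                 params = params),
            class = "est_clustering")
}

#' @export
print.est_clustering <- function(x, ...) {
  cat(sprintf("EST clustering: %d reads in %d clusters (%d singletons)\n",
              nrow(x$members), x$n_clusters, x$n_singletons))
  invisible(x)
}

# Majority-rule consensus of one cluster. Reads are laid out greedily from
# the accepted pairwise offsets (BFS over the overlap edges); an edge whose
# offset conflicts with the layout already fixed is dropped with a warning.
# Per column: majority base over covering reads, ties broken A < C < G < T,
# N ignored unless the column is all-N.
consensus <- function(seqs, ids, edges, orig_index) {
  m <- length(seqs)
  if (m == 1L) return(seqs[[1L]])
  local <- match(vapply(edges, `[[`, integer(1), "i"), orig_index)
  localj <- match(vapply(edges, `[[`, integer(1), "j"), orig_index)
  offs <- vapply(edges, `[[`, numeric(1), "offset")
  pos <- rep(NA_real_, m)
  pos[1L] <- 0
  queue <- 1L
  active <- rep(TRUE, length(edges))
  while (length(queue)) {
    u <- queue[1L]; queue <- queue[-1L]
    for (e in which(active)) {
      i <- local[e]; j <- localj[e]
      if (i == u && is.na(pos[j])) {
        pos[j] <- pos[u] + offs[e]; queue <- c(queue, j)
      } else if (j == u && is.na(pos[i])) {
        pos[i] <- pos[u] - offs[e]; queue <- c(queue, i)
      } else if ((i == u || j == u) && !is.na(pos[i]) && !is.na(pos[j])) {
        if (pos[j] - pos[i] != offs[e]) {
          warning("inconsistent overlap layout in cluster containing ",
                  ids[1L], "; conflicting overlap dropped")
        }
        active[e] <- FALSE
      }
    }
  }
  if (anyNA(pos)) pos[is.na(pos)] <- 0  # disconnected within component
  pos <- pos - min(pos)
  width <- max(pos + nchar(seqs))
  counts <- matrix(0L, nrow = 5L, ncol = width,
                   dimnames = list(c("A", "C", "G", "T", "N"), NULL))
  for (r in seq_len(m)) {
    ch <- strsplit(seqs[[r]], "")[[1L]]
    cols <- pos[r] + seq_along(ch)
    for (b in c("A", "C", "G", "T", "N")) {
      hit <- cols[ch == b]
      counts[b, hit] <- counts[b, hit] + 1L
    }
  }
  base_counts <- counts[1:4, , drop = FALSE]
  covered <- colSums(counts) > 0
  pick <- apply(base_counts, 2L, function(col) {
    if (all(col == 0L)) "N" else rownames(base_counts)[which.max(col)]
  })
  paste(pick[covered], collapse = "")
}
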