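#' Three-frame translation of an EST
#'
#' Translates the forward strand in frames 1-3 under the standard genetic
#' code. Reverse-complement frames are deliberately not produced: the cDNA
#' libraries this pipeline models are unidirectional. Stops are rendered
#' \code{*}; a trailing partial codon is dropped; codons containing \code{N}
#' translate to \code{X} unless the residue is determined regardless of the
#' ambiguity.
#'
#' @param seq Nucleotide sequence, length >= 3.
#' @return Character vector of the three frame translations (a frame shorter
#'   than one codon gives \code{""}).
#' @export
three_frame_translate <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) < 3L) stop("sequence shorter than one codon")
  if (!grepl("^[ACGTN]+$", seq)) stop("not a nucleotide sequence")
  vapply(1:3, function(f) {
    sub <- substr(seq, f, nchar(seq))
    n <- nchar(sub) - nchar(sub) %% 3L
    if (n < 3L) return("")
    as.character(Biostrings::translate(
      Biostrings::DNAString(substr(sub, 1L, n)),
      if.fuzzy.codon = "solve"))
  }, character(1))
}

#' Select the reportable ORF from three frame translations
#'
#' In each frame the candidate is the segment from the first methionine
#' found within the first 300 predicted residues to the first following stop
#' (or the end of the frame if no stop is observed). The longest candidate
#' across frames is reported; ties go to the lower frame number.
#'
#' @param translations Character vector of 3 frame translations, as from
#'   [three_frame_translate()].
#' @param met_window How deep into each frame (in residues) a starting
#'   methionine may sit (default 300).
#' @return A list with \code{frame}, \code{start_nt} (0-based offset of the
#'   A of the start codon in the nucleotide sequence), \code{protein} and
#'   \code{complete_cds} (stop codon observed), or \code{NULL} when no frame
#'   has a methionine within the window.
#' @export
select_orf <- function(translations, met_window = 300L) {
  stopifnot(length(translations) == 3L)
  cand <- lapply(1:3, function(f) {
    tr <- translations[f]
    if (!nzchar(tr)) return(NULL)
    m <- regexpr("M", substr(tr, 1L, met_window), fixed = TRUE)
    if (m < 0L) return(NULL)
    rest <- substr(tr, m, nchar(tr))
    stop_at <- regexpr("*", rest, fixed = TRUE)
    prot <- if (stop_at > 0L) substr(rest, 1L, stop_at - 1L) else rest
    list(frame = f, start_nt = (f - 1L) + 3L * (as.integer(m) - 1L),
         protein = prot, complete_cds = stop_at > 0L)
  })
  cand <- Filter(Negate(is.null), cand)
  if (!length(cand)) return(NULL)
  lens <- vapply(cand, function(x) nchar(x$protein), integer(1))
  cand[[which.max(lens)]]  # which.max takes the first (lowest frame) on ties
}

#' Heuristic signal-peptide call
#'
#' A deliberately simple stand-in for a trained signal-peptide predictor,
#' capturing the canonical architecture: within the first 30 residues, an
#' uninterrupted hydrophobic core (h-region) of at least \code{min_h}
#' residues from \{A,I,L,F,V,M,W,C\}, followed within 10 residues by a
#' small-residue position from \{A,G,S,C,T\} resembling a cleavage site.
#' When an annotation-evidence table carries a real predictor's yes/no call,
#' that call overrides this heuristic (see [classify_record()]).
#'
#' @param protein Amino-acid sequence starting with M.
#' @param min_h Minimum h-region length (default 8).
#' @param search_window How far into the protein the h-region may start
#'   (default 30 residues).
#' @return A list with \code{call} (\code{"yes"}, \code{"no"} or
#'   \code{"unknown"} for proteins shorter than 25 residues) and
#'   \code{score} (the h-window length, 0 when absent).
#' @export
predict_secretion <- function(protein, min_h = 8L, search_window = 30L) {
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWYX]*$", protein)) {
    stop("non-amino-acid characters in protein")
  }
  if (nchar(protein) < 25L) return(list(call = "unknown", score = 0L))
  head30 <- substr(protein, 1L, search_window)
  ch <- strsplit(head30, "")[[1L]]
  hydro <- ch %in% c("A", "I", "L", "F", "V", "M", "W", "C")
  runs <- rle(hydro)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ok <- which(runs$values & runs$lengths >= min_h)
  full <- strsplit(protein, "")[[1L]]
  for (r in ok) {
    after <- seq(ends[r] + 1L, min(ends[r] + 10L, length(full)))
    if (length(after) &&
        any(full[after] %in% c("A", "G", "S", "C", "T"))) {
      return(list(call = "yes", score = runs$lengths[r]))
    }
  }
  list(call = "no", score = if (length(ok)) max(runs$lengths[ok]) else 0L)
}

.sialome_env <- new.env(parent = emptyenv())

#' Keyword vocabularies for functional classification
#'
#' Loads the controlled subcategory vocabularies (19 housekeeping subgroups,
#' 24 secreted families) with the keyword patterns used to match best-hit
#' descriptions. Shipped as editable TSVs under \code{extdata} so a curator
#' can extend the keyword lists without touching code.
#'
#' @return A list with data frames \code{H} and \code{S}, each with columns
#'   \code{subcategory} and \code{pattern} (a case-insensitive regular
#'   expression).
#' @export
class_keywords <- function() {
  if (is.null(.sialome_env$keywords)) {
    load1 <- function(f) {
      utils::read.delim(system.file("extdata", f, package = "sialome",
                                    mustWork = TRUE),
                        stringsAsFactors = FALSE)
    }
    .sialome_env$keywords <- list(H = load1("h_subgroups.tsv"),
                                  S = load1("s_families.tsv"))
  }
  .sialome_env$keywords
}

match_subcategory <- function(description, vocab) {
  if (!nzchar(description)) return(NA_character_)
  hit <- which(vapply(vocab$pattern, function(p)
    grepl(p, description, ignore.case = TRUE, perl = TRUE), logical(1)))
  if (length(hit)) vocab$subcategory[hit[1L]] else NA_character_
}

informative_hit <- function(description) {
  nzchar(description) &&
    !grepl("hypothetical|uncharacterized|unknown protein|no hit",
           description, ignore.case = TRUE)
}

#' Assign a housekeeping / secreted / unknown class
#'
#' Rule cascade, first match wins:
#' \enumerate{
#'   \item an explicit \code{category_hint} in the evidence row is used
#'     verbatim (format \code{"U"}, \code{"H:<subgroup>"} or
#'     \code{"S:<family>"}; subcategories outside the controlled
#'     vocabularies are rejected);
#'   \item secretion "yes" and a best hit matching a secreted-family keyword
#'     (or no informative hit at all) gives S with the matched family (or
#'     \code{"unknown"});
#'   \item an informative hit matching a housekeeping subgroup keyword gives
#'     H with that subgroup;
#'   \item otherwise U.
#' }
#' The secretion call is the evidence row's \code{signal_peptide} when
#' present (a real predictor's output), falling back to
#' [predict_secretion()] on the deduced protein.
#'
#' @param protein Deduced protein sequence (may be \code{NA} when no ORF).
#' @param evidence One row of an evidence table (see [read_evidence()]), or
#'   \code{NULL}.
#' @return A list with \code{major} (\code{"H"}, \code{"S"} or \code{"U"}),
#'   \code{subcategory} (\code{NA} for U) and \code{secretion}.
#' @export
classify_record <- function(protein, evidence = NULL) {
  kw <- class_keywords()
  hit <- if (!is.null(evidence)) evidence$best_hit_description else ""
  hint <- if (!is.null(evidence)) evidence$category_hint else ""
  secretion <- if (!is.null(evidence) &&
                   evidence$signal_peptide %in% c("yes", "no")) {
    evidence$signal_peptide
  } else if (!is.na(protein) && nzchar(protein) &&
             startsWith(protein, "M")) {
    predict_secretion(protein)$call
  } else {
    "unknown"
  }
  if (nzchar(hint)) {
    if (hint == "U") {
      return(list(major = "U", subcategory = NA_character_,
                  secretion = secretion))
    }
    parts <- strsplit(hint, ":", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || !parts[1L] %in% c("H", "S") ||
        !parts[2L] %in% kw[[parts[1L]]]$subcategory) {
      stop("category_hint outside the controlled vocabulary: ", hint)
    }
    return(list(major = parts[1L], subcategory = parts[2L],
                secretion = secretion))
  }
  if (secretion == "yes") {
    sub <- match_subcategory(hit, kw$S)
    if (!is.na(sub)) {
      return(list(major = "S", subcategory = sub, secretion = secretion))
    }
    if (!informative_hit(hit)) {
      return(list(major = "S", subcategory = "unknown",
                  secretion = secretion))
    }
  }
  if (informative_hit(hit)) {
    sub <- match_subcategory(hit, kw$H)
    if (!is.na(sub)) {
      return(list(major = "H", subcategory = sub, secretion = secretion))
    }
  }
  list(major = "U", subcategory = NA_character_, secretion = secretion)
}

#' Annotate a set of transcripts
#'
#' Runs [three_frame_translate()], [select_orf()] and [classify_record()]
#' over a sequence table, joining evidence rows by id.
#'
#' @param seqs Data frame with \code{id} and \code{seq} (nucleotide).
#' @param evidence Evidence table from [read_evidence()], or \code{NULL}.
#' @param est_count Optional integer vector of per-transcript EST counts
#'   (cluster sizes); defaults to 1 each.
#' @return A data frame with one row per input: id, frame, ORF span,
#'   protein, completeness, secretion call, major class, subcategory and
#'   est_count.
#' @export
annotate_transcripts <- function(seqs, evidence = NULL, est_count = NULL) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  if (is.null(est_count)) est_count <- rep(1L, nrow(seqs))
  stopifnot(length(est_count) == nrow(seqs), all(est_count >= 1L))
  rows <- lapply(seq_len(nrow(seqs)), function(i) {
    orf <- select_orf(three_frame_translate(seqs$seq[i]))
    ev <- if (!is.null(evidence) && seqs$id[i] %in% evidence$id) {
      evidence[match(seqs$id[i], evidence$id), , drop = FALSE]
    } else {
      NULL
    }
    prot <- if (is.null(orf)) NA_character_ else orf$protein
    cls <- classify_record(prot, ev)
    data.frame(
      id = seqs$id[i],
      frame = if (is.null(orf)) NA_integer_ else orf$frame,
      start_nt = if (is.null(orf)) NA_integer_ else orf$start_nt,
      protein = prot,
      complete_cds = if (is.null(orf)) NA else orf$complete_cds,
      secretion = cls$secretion,
      major = cls$major,
      subcategory = cls$subcategory,
      est_count = est_count[i],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' EST-weighted class and subcategory abundance table
#'
#' Reproduces the bookkeeping of published sialotranscriptome tables: per
#' major class, the EST-weighted count and percent of the library; within
#' the H and S classes, each subcategory's percent of its group, all to one
#' decimal with half-up rounding.
#'
#' @param records Annotated records from [annotate_transcripts()] (needs
#'   \code{major}, \code{subcategory}, \code{est_count}).
#' @return A list with data frames \code{major} (class, ests, percent) and
#'   \code{subcategories} (class, subcategory, ests, percent_of_group).
#' @export
category_table <- function(records) {
  stopifnot(all(c("major", "subcategory", "est_count") %in% names(records)))
  total <- sum(records$est_count)
  maj <- stats::aggregate(est_count ~ major, records, sum)
  maj$percent <- percent_of_group(maj$est_count, total)
  names(maj) <- c("class", "ests", "percent")
  subs <- records[records$major %in% c("H", "S") &
                    !is.na(records$subcategory), ]
  if (nrow(subs)) {
    sc <- stats::aggregate(est_count ~ major + subcategory, subs, sum)
    group_tot <- maj$ests[match(sc$major, maj$class)]
    sc$percent_of_group <- percent_of_group(sc$est_count, group_tot)
    names(sc) <- c("class", "subcategory", "ests", "percent_of_group")
    sc <- sc[order(sc$class, -sc$ests, sc$subcategory), ]
    rownames(sc) <- NULL
  } else {
    sc <- data.frame(class = character(0), subcategory = character(0),
                     ests = integer(0), percent_of_group = numeric(0))
  }
  list(major = maj, subcategories = sc)
}
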