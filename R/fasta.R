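#' Read a FASTA file into a sequence table
#'
#' Parses a nucleotide or protein FASTA file into a data frame with one row
#' per record. Sequences may be wrapped at any width; lines are concatenated
#' and uppercased. A trailing \code{*} (translation stop) is stripped from
#' protein sequences.
#'
#' @param path Path to a FASTA file.
#' @param alphabet Either \code{"nucleotide"} or \code{"protein"}. Controls
#'   which residue characters are accepted (\code{N} respectively \code{X}
#'   stand for unknowns).
#' @return A data frame with columns \code{id}, \code{desc} and \code{seq},
#'   in file order.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a first", "ACGT", ">b", "GGG", "TTT"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !any(nzchar(trimws(lines)))) {
    stop("empty FASTA file: ", path)
  }
  hdr <- grepl("^>", lines)
  if (!hdr[match(TRUE, nzchar(trimws(lines)))]) {
    stop("FASTA parse error at line ",
         match(TRUE, nzchar(trimws(lines))), ": expected '>' header")
  }
  idx <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) {
    stop("FASTA parse error at line ", which(hdr)[!nzchar(ids)][1L],
         ": empty sequence id")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  }
  body <- !hdr & nzchar(trimws(lines))
  seqs <- vapply(seq_along(ids), function(i) {
    toupper(paste(gsub("\\s", "", lines[body & idx == i]), collapse = ""))
  }, character(1))
  if (alphabet == "protein") seqs <- sub("\\*$", "", seqs)
  ok_chars <- if (alphabet == "nucleotide") "^[ACGTN]*$" else
    "^[ACDEFGHIKLMNPQRSTVWYX]*$"
  bad <- !grepl(ok_chars, seqs)
  if (any(bad)) {
    stop("illegal ", alphabet, " characters in record '", ids[bad][1L], "'")
  }
  if (any(!nzchar(seqs))) {
    stop("record '", ids[!nzchar(seqs)][1L], "' has an empty sequence")
  }
  data.frame(id = ids, desc = desc, seq = seqs, stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param x A data frame with columns \code{id} and \code{seq} (and
#'   optionally \code{desc}), or a named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 70 columns).
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.character(x)) {
    x <- data.frame(id = names(x), desc = "", seq = unname(x),
                    stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "seq") %in% names(x)))
  desc <- if ("desc" %in% names(x)) x$desc else rep("", nrow(x))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    header <- if (nzchar(desc[i])) paste0(">", x$id[i], " ", desc[i]) else
      paste0(">", x$id[i])
    writeLines(header, con)
    s <- x$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read an annotation-evidence table
#'
#' Reads a TSV standing in for BLAST / conserved-domain / signal-peptide
#' search output. Recognised columns: \code{id}, \code{best_hit_description},
#' \code{domain_tags} (comma-separated), \code{signal_peptide}
#' (\code{yes}/\code{no}/\code{unknown}) and \code{category_hint}. Unknown
#' columns are ignored; missing optional columns are filled with defaults so
#' heterogeneous annotation exports load without editing.
#'
#' @param path Path to a tab-separated file with a header line.
#' @return A data frame with the five canonical columns.
#' @export
read_evidence <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#", check.names = FALSE)
  if (!"id" %in% names(ev)) stop("evidence table lacks an 'id' column")
  if (anyDuplicated(ev$id)) {
    stop("duplicate id in evidence table: ", ev$id[duplicated(ev$id)][1L])
  }
  fill <- function(col, default) {
    if (col %in% names(ev)) as.character(ev[[col]]) else
      rep(default, nrow(ev))
  }
  out <- data.frame(
    id = as.character(ev$id),
    best_hit_description = fill("best_hit_description", ""),
    domain_tags = fill("domain_tags", ""),
    signal_peptide = fill("signal_peptide", "unknown"),
    category_hint = fill("category_hint", ""),
    stringsAsFactors = FALSE
  )
  out$best_hit_description[is.na(out$best_hit_description)] <- ""
  out$category_hint[is.na(out$category_hint)] <- ""
  out$signal_peptide[is.na(out$signal_peptide)] <- "unknown"
  bad <- !out$signal_peptide %in% c("yes", "no", "unknown")
  if (any(bad)) {
    stop("signal_peptide must be yes/no/unknown; offending id: ",
         out$id[bad][1L])
  }
  out
}

#' Write a report table with a provenance header
#'
#' All pipeline outputs start with comment lines recording the package
#' version, the producing stage and a hash of the configuration used, so a
#' result file is traceable to the run that made it.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param stage Name of the producing pipeline stage.
#' @param config Optional list of parameters; hashed into the header.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(x, path, stage, config = list()) {
  ver <- as.character(utils::packageVersion("sialome"))
  cfg <- paste(deparse(config, width.cutoff = 500L), collapse = " ")
  hash <- sprintf("%08x", sum(utf8ToInt(cfg) * seq_along(utf8ToInt(cfg))) %%
                    .Machine$integer.max)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# sialome %s", ver),
    sprintf("# stage: %s", stage),
    sprintf("# config_hash: %s", hash)
  ), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
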