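# Contig sets are named character vectors: names are contig ids, values are
# upper-case DNA over {A,C,G,T,N}. Fragments are data frames with 0-based
# half-open coordinates into their parent contig.

normalize_bases <- function(x) {
  x <- toupper(x)
  gsub("[^ACGT]", "N", x, perl = TRUE)
}

as_contigs <- function(x) {
  if (is.character(x) && length(x) == 1 && is.null(names(x)) && file.exists(x)) {
    return(read_fasta(x))
  }
  if (!is.character(x)) stopf("contigs must be a named character vector or a FASTA path")
  if (length(x) > 0 && (is.null(names(x)) || any(!nzchar(names(x))))) {
    stopf("every contig needs a non-empty id (vector name)")
  }
  dup <- unique(names(x)[duplicated(names(x))])
  if (length(dup)) stopf("duplicate contig ids: %s", paste(dup, collapse = ", "))
  setNames(normalize_bases(x), names(x))
}

#' Read contigs from a FASTA file
#'
#' Reads plain or line-wrapped FASTA. The id of each contig is the header
#' token up to the first whitespace; sequences are upper-cased and any
#' letter outside `{A,C,G,T}` is mapped to `N`.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of contig sequences (names are ids).
#'   An empty file yields an empty vector.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">c1 a description", "acgtACGT"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0) return(setNames(character(0), character(0)))
  if (!startsWith(first, ">")) {
    stopf("malformed FASTA in %s: line 1 does not start with '>'", path)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) stopf("malformed FASTA in %s: empty record id", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) stopf("duplicate contig ids in %s: %s", path, paste(dup, collapse = ", "))
  setNames(normalize_bases(as.character(set)), ids)
}

#' Write contigs to a FASTA file
#'
#' Round-trip safe with [read_fasta()]: ids and sequences are reproduced
#' exactly.
#'
#' @param contigs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(contigs, path, width = 70) {
  contigs <- as_contigs(contigs)
  set <- Biostrings::BStringSet(contigs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Discard contigs shorter than a minimum length
#'
#' Assemblies of amplified single cells carry many short, unreliable
#' contigs; the conventional cutoff of 500 bp is the default.
#'
#' @param contigs Named character vector of sequences.
#' @param min_len Minimum retained length in bp (default 500).
#' @return The contigs with length `>= min_len`, order preserved.
#' @export
filter_min_length <- function(contigs, min_len = 500) {
  if (!is_count(min_len, min = 1)) stopf("min_len must be a positive integer")
  contigs[nchar(contigs) >= min_len]
}

#' Split contigs into fixed-length fragments
#'
#' Each contig is cut into consecutive windows of `frag_len` bp (1000 bp by
#' default). A trailing partial window is kept when it is at least half of
#' `frag_len`, otherwise dropped: composition estimates on very short
#' windows are too noisy to help.
#'
#' @param contigs Named character vector of sequences.
#' @param frag_len Window length in bp (default 1000, minimum 100).
#' @return Data frame with one row per fragment: `parent_id`, `index`
#'   (0-based within parent), `start`, `end` (0-based half-open offsets)
#'   and `sequence`.
#' @export
#' @examples
#' frs <- fragment_contigs(c(c1 = strrep("ACGT", 625)), frag_len = 1000)
#' frs[, c("parent_id", "index", "start", "end")]
fragment_contigs <- function(contigs, frag_len = 1000) {
  contigs <- as_contigs(contigs)
  if (!is_count(frag_len, min = 100)) stopf("frag_len must be an integer >= 100")
  pieces <- lapply(names(contigs), function(id) {
    L <- nchar(contigs[[id]])
    n_full <- L %/% frag_len
    rem <- L %% frag_len
    keep_tail <- rem > 0 && rem >= frag_len / 2
    n <- n_full + as.integer(keep_tail)
    if (n == 0) return(NULL)
    start <- (seq_len(n) - 1L) * frag_len
    end <- pmin(start + frag_len, L)
    data.frame(
      parent_id = id, index = seq_len(n) - 1L, start = start, end = end,
      sequence = substring(contigs[[id]], start + 1L, end),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(
      parent_id = character(0), index = integer(0), start = integer(0),
      end = integer(0), sequence = character(0), stringsAsFactors = FALSE
    )
  }
  rownames(out) <- NULL
  out
}

#' Write a per-contig confidence table as TSV
#'
#' Columns: `contig_id`, `n_fragments`, `confidence` (0--1) and
#' `confidence_pct` (0--100, one decimal). Contigs whose fragments were all
#' invalid for composition analysis carry `NA`.
#'
#' @param table A score table as returned by [score_contigs()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @seealso [read_scores_tsv()]
#' @export
write_scores_tsv <- function(table, path) {
  need <- c("contig_id", "n_fragments", "confidence")
  if (!all(need %in% names(table))) {
    stopf("score table needs columns: %s", paste(need, collapse = ", "))
  }
  body <- if (nrow(table) > 0) {
    conf <- ifelse(is.na(table$confidence), "NA",
                   sprintf("%.15g", table$confidence))
    pct <- ifelse(is.na(table$confidence), "NA",
                  sprintf("%.1f", 100 * table$confidence))
    sprintf("%s\t%d\t%s\t%s", table$contig_id, as.integer(table$n_fragments), conf, pct)
  } else character(0)
  writeLines(c("contig_id\tn_fragments\tconfidence\tconfidence_pct", body), path)
  invisible(path)
}

#' Read a confidence table written by [write_scores_tsv()]
#'
#' @param path Path to the TSV.
#' @return Data frame with the score-table columns.
#' @export
read_scores_tsv <- function(path) {
  if (!file.exists(path)) stopf("score TSV not found: %s", path)
  read.table(path, header = TRUE, sep = "\t", colClasses = c(
    contig_id = "character", n_fragments = "integer",
    confidence = "numeric", confidence_pct = "numeric"
  ), stringsAsFactors = FALSE)
}
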