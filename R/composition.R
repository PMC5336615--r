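# Sequence-composition features and the shared 2-D embedding. Fragments from
# every dataset (sample SAG, no-template control, optional reference) are
# pooled before the PCA fit so that all datasets live in one coordinate
# system -- the subtraction of densities downstream requires comparable axes.

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' GC content of a sequence
#'
#' `(#G + #C) / (#A + #C + #G + #T)`; `N` bases count in neither numerator
#' nor denominator.
#'
#' @param sequence DNA string (case-insensitive; non-ACGT letters treated as N).
#' @return Fraction in `[0, 1]`, or `NA` when the sequence has no countable
#'   base (invalid-fragment signal).
#' @export
#' @examples
#' gc_content("ATGC") # 0.5
#' gc_content("ANGT") # 1/3
gc_content <- function(sequence) {
  s <- Biostrings::DNAStringSet(normalize_bases(sequence))
  cnt <- Biostrings::letterFrequency(s, c("A", "C", "G", "T"))[1, ]
  denom <- sum(cnt)
  if (denom == 0) return(NA_real_)
  unname((cnt[["G"]] + cnt[["C"]]) / denom)
}

kmer_count_matrix <- function(sequences, k) {
  set <- Biostrings::DNAStringSet(normalize_bases(sequences))
  fwd <- Biostrings::oligonucleotideFrequency(set, width = k)
  rev <- Biostrings::oligonucleotideFrequency(Biostrings::reverseComplement(set), width = k)
  fwd + rev
}

#' Strand-symmetrized k-mer frequencies
#'
#' Counts every overlapping window of length `k` on the sequence and on its
#' reverse complement (so the frequencies of a sequence and of its reverse
#' complement are identical), skips windows containing `N`, and normalizes
#' to sum 1.
#'
#' @param sequence DNA string.
#' @param k Word length (default 4: tetranucleotides, the community
#'   standard for composition binning).
#' @return Named vector of `4^k` frequencies in lexicographic k-mer order,
#'   or all-`NA` when no window is countable (invalid-fragment signal).
#' @export
#' @examples
#' kmer_frequencies("AAAA", k = 1) # A and T both 0.5
kmer_frequencies <- function(sequence, k = 4) {
  if (!is_count(k, min = 1)) stopf("k must be a positive integer")
  if (nchar(sequence) < k) stopf("sequence shorter than k")
  counts <- kmer_count_matrix(sequence, k)[1, ]
  tot <- sum(counts)
  if (tot == 0) return(setNames(rep(NA_real_, length(counts)), names(counts)))
  counts / tot
}

codon_families <- function() {
  code <- Biostrings::GENETIC_CODE
  code <- code[code != "*"]
  split(names(code), unname(code))
}

#' Relative synonymous codon usage (RSCU)
#'
#' For codon *j* with count `x_j` in a synonymous family of size `n_j`,
#' `RSCU_j = n_j * x_j / sum(x over the family)`: the observed count divided
#' by the count expected under uniform usage within the family. Values lie
#' in `[0, n_j]` and average 1 over any family with nonzero total. Stop
#' codons are excluded; a family with zero total count yields 0 for all its
#' members.
#'
#' @param codon_counts Named numeric vector of codon counts (names are
#'   codons, e.g. `"AAA"`); codons not supplied count 0.
#' @return Named vector over all 61 sense codons, lexicographic order.
#' @export
#' @examples
#' rscu(c(AAA = 3, AAG = 1))[c("AAA", "AAG")] # 1.5, 0.5
rscu <- function(codon_counts) {
  if (any(codon_counts < 0, na.rm = TRUE)) stopf("codon counts must be non-negative")
  fams <- codon_families()
  codons <- sort(unlist(fams, use.names = FALSE))
  bad <- setdiff(names(codon_counts), names(Biostrings::GENETIC_CODE))
  if (length(bad)) stopf("not a codon: %s", paste(bad, collapse = ", "))
  out <- setNames(numeric(length(codons)), codons)
  for (members in fams) {
    x <- ifelse(members %in% names(codon_counts), codon_counts[members], 0)
    tot <- sum(x)
    if (tot > 0) out[members] <- length(members) * x / tot
  }
  out
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

orf_scan_strand <- function(s, min_len) {
  L <- nchar(s)
  hits <- NULL
  for (frame in 0:2) {
    n_codon <- (L - frame) %/% 3
    if (n_codon < 1) next
    starts <- frame + seq_len(n_codon) * 3 - 2 # 1-based codon starts
    codons <- substring(s, starts, starts + 2)
    open_at <- NA_integer_
    for (i in seq_len(n_codon)) {
      if (codons[i] %in% STOP_CODONS) {
        if (!is.na(open_at)) {
          st <- starts[open_at] - 1L # 0-based
          en <- starts[i] + 2L
          if (en - st >= min_len) hits <- rbind(hits, c(st, en))
          open_at <- NA_integer_
        }
      } else if (is.na(open_at) && codons[i] == "ATG") {
        open_at <- i
      }
    }
  }
  hits
}

#' Find open reading frames on both strands
#'
#' Scans all six frames for maximal ATG-to-stop open reading frames (the
#' leftmost ATG in each stop-bounded segment, so ORFs within one frame are
#' non-nested). Used to gather codon counts for [rscu()]; it is a simple
#' ORF caller, not a gene predictor.
#'
#' @param sequence DNA string.
#' @param min_len Minimum ORF length in bp, ATG through stop inclusive
#'   (default 90).
#' @return Data frame with `start`, `end` (0-based half-open, forward-strand
#'   coordinates) and `strand` (`"+"`/`"-"`), ordered by start.
#' @export
find_orfs <- function(sequence, min_len = 90) {
  s <- normalize_bases(sequence)
  L <- nchar(s)
  fwd <- orf_scan_strand(s, min_len)
  rev <- orf_scan_strand(revcomp(s), min_len)
  rows <- list()
  if (!is.null(fwd)) {
    rows$f <- data.frame(start = fwd[, 1], end = fwd[, 2], strand = "+",
                         stringsAsFactors = FALSE)
  }
  if (!is.null(rev)) {
    rows$r <- data.frame(start = L - rev[, 2], end = L - rev[, 1], strand = "-",
                         stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Codon counts over the ORFs of a sequence
#'
#' @param sequence DNA string.
#' @param min_len Minimum ORF length passed to [find_orfs()].
#' @return Named integer vector of codon counts pooled over all ORFs
#'   (reading strand), stop codons included (they are ignored by [rscu()]).
#' @export
codon_counts <- function(sequence, min_len = 90) {
  s <- normalize_bases(sequence)
  orfs <- find_orfs(s, min_len = min_len)
  if (nrow(orfs) == 0) return(setNames(integer(0), character(0)))
  cds <- mapply(function(st, en, strand) {
    sub <- substring(s, st + 1, en)
    if (strand == "-") revcomp(sub) else sub
  }, orfs$start, orfs$end, orfs$strand)
  codons <- unlist(lapply(cds, function(x) {
    substring(x, seq(1, nchar(x) - 2, by = 3), seq(3, nchar(x), by = 3))
  }))
  tab <- table(codons)
  setNames(as.integer(tab), names(tab))
}

#' Build a per-fragment composition feature matrix
#'
#' @param sequences Character vector of fragment sequences.
#' @param kind Feature space: `"kmer"` (k-mer frequencies, the default),
#'   `"gc"` (single GC-content column) or `"codon"` (per-codon RSCU over
#'   the fragment's ORFs).
#' @param k Word length for `kind = "kmer"`.
#' @return Numeric matrix, one row per sequence, columns in fixed
#'   lexicographic feature order, with attributes `feature_kind` and
#'   `valid` (logical: rows with no countable feature are all-zero and
#'   flagged invalid).
#' @export
feature_matrix <- function(sequences, kind = c("kmer", "gc", "codon"), k = 4) {
  kind <- match.arg(kind)
  if (kind == "kmer") {
    counts <- kmer_count_matrix(sequences, k)
    tot <- rowSums(counts)
    valid <- tot > 0
    mat <- counts / ifelse(tot > 0, tot, 1)
  } else if (kind == "gc") {
    gc <- vapply(sequences, gc_content, numeric(1), USE.NAMES = FALSE)
    valid <- !is.na(gc)
    mat <- cbind(GC = ifelse(valid, gc, 0))
  } else {
    rows <- lapply(sequences, function(s) rscu(codon_counts(s)))
    mat <- do.call(rbind, rows)
    orf_found <- vapply(sequences, function(s) nrow(find_orfs(s)) > 0, logical(1),
                        USE.NAMES = FALSE)
    valid <- orf_found & rowSums(mat) > 0
    mat[!valid, ] <- 0
  }
  mat <- as.matrix(mat)
  structure(mat, feature_kind = kind, valid = valid)
}

#' Embed fragments into a shared 2-D composition space
#'
#' Fits a PCA (column centering, no scaling) on the pooled rows of all
#' datasets being co-analyzed and projects every valid fragment onto the
#' first two principal components. Pooling is essential: the sample,
#' control and any reference must share one coordinate system for their
#' densities to be comparable. Sign convention: each component's loading
#' vector is flipped so that its largest-magnitude entry is positive, which
#' makes the embedding deterministic.
#'
#' @param features Matrix from [feature_matrix()] (pooled over datasets).
#' @param tags Per-row dataset tag (e.g. `"sample"`, `"control"`,
#'   `"reference"`); recycled if length 1.
#' @param parent_id,index Optional per-row fragment identity, carried
#'   through for scoring.
#' @return Data frame of class `embedded_points` with columns `x`, `y`,
#'   `dataset`, `parent_id`, `index` (valid rows only), and attributes
#'   `center` and `rotation` for projecting new data.
#' @export
embed_2d <- function(features, tags = "sample", parent_id = NULL, index = NULL) {
  valid <- attr(features, "valid") %||% rep(TRUE, nrow(features))
  if (ncol(features) < 2) {
    stopf("need >= 2 feature columns for a 2-D embedding; try a different feature_kind")
  }
  X <- features[valid, , drop = FALSE]
  if (nrow(X) < 3) stopf("need >= 3 valid fragments to fit the embedding")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  if (length(pc$sdev) < 2 || pc$sdev[2] <= 1e-12 * pc$sdev[1]) {
    stopf("feature matrix has rank < 2; try a different feature_kind")
  }
  rot <- pc$rotation[, 1:2, drop = FALSE]
  for (j in 1:2) {
    m <- which.max(abs(rot[, j]))
    if (rot[m, j] < 0) rot[, j] <- -rot[, j]
  }
  scores <- sweep(X, 2, pc$center) %*% rot
  tags <- rep_len(as.character(tags), nrow(features))
  pts <- data.frame(
    x = scores[, 1], y = scores[, 2],
    dataset = tags[valid],
    parent_id = if (!is.null(parent_id)) parent_id[valid] else NA_character_,
    index = if (!is.null(index)) index[valid] else NA_integer_,
    stringsAsFactors = FALSE
  )
  rownames(pts) <- NULL
  structure(pts, center = pc$center, rotation = rot,
            class = c("embedded_points", "data.frame"))
}

# Project new feature rows into an existing embedding.
project_features <- function(features, center, rotation) {
  sweep(features, 2, center) %*% rotation
}

#' Export a feature matrix as TSV for inspection
#'
#' @param features Matrix from [feature_matrix()].
#' @param keys Per-row fragment keys.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_features_tsv <- function(features, keys, path) {
  df <- data.frame(fragment = keys, features, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
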