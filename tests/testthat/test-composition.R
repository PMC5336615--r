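test_that("gc_content counts G+C over countable bases only", {
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ANGT"), 1 / 3)
  expect_equal(gc_content("atgc"), 0.5)
  expect_true(is.na(gc_content("NNNN")))
})

test_that("kmer_frequencies is strand-symmetrized, skips N, sums to 1", {
  f1 <- kmer_frequencies("AAAA", k = 1)
  expect_equal(unname(f1[c("A", "T", "C", "G")]), c(0.5, 0.5, 0, 0))

  f4 <- kmer_frequencies("ACGT", k = 4)
  expect_equal(unname(f4[["ACGT"]]), 1.0)

  set.seed(7)
  for (i in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 60, TRUE, prob = c(rep(0.24, 4), 0.04)),
               collapse = "")
    f <- kmer_frequencies(s, k = 3)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(f, kmer_frequencies(rc, k = 3))
    expect_equal(sum(f), 1, tolerance = 1e-9)
  }

  expect_true(all(is.na(kmer_frequencies("ANNNA", k = 2)))) # no countable window
  expect_error(kmer_frequencies("AC", k = 4), "shorter")
})

test_that("rscu follows the synonymous-family formula", {
  r <- rscu(c(AAA = 2, AAG = 2)) # Lys family, n_j = 2, uniform usage
  expect_equal(unname(r[c("AAA", "AAG")]), c(1, 1))

  r <- rscu(c(AAA = 3, AAG = 1))
  expect_equal(unname(r[c("AAA", "AAG")]), c(1.5, 0.5))

  r <- rscu(c(AAA = 1)) # every other family has zero total -> all zeros
  expect_equal(unname(r[c("GGA", "GGC", "GGG", "GGT")]), rep(0, 4))

  expect_length(r, 61) # sense codons only
  expect_false(any(c("TAA", "TAG", "TGA") %in% names(r)))
  expect_error(rscu(c(AAA = -1)), "non-negative")
  expect_error(rscu(c(XYZ = 1)), "not a codon")
})

test_that("RSCU of a family lies in [0, n_j] and averages 1 when used", {
  set.seed(11)
  counts <- setNames(rpois(64, 5), names(Biostrings::GENETIC_CODE))
  counts <- counts[Biostrings::GENETIC_CODE != "*"]
  r <- rscu(counts)
  fams <- split(names(r), unname(Biostrings::GENETIC_CODE[names(r)]))
  for (members in fams) {
    vals <- r[members]
    expect_true(all(vals >= 0 & vals <= length(members) + 1e-12))
    if (sum(counts[members]) > 0) expect_equal(mean(vals), 1, tolerance = 1e-12)
  }
})

test_that("find_orfs reports maximal ATG-to-stop frames on both strands", {
  o <- find_orfs("ATGAAATAA", min_len = 9)
  expect_equal(nrow(o), 1)
  expect_equal(o$start, 0)
  expect_equal(o$end, 9)
  expect_equal(o$strand, "+")

  expect_equal(nrow(find_orfs("CCCCCCTAACCC", min_len = 3)), 0) # no ATG

  # leftmost ATG wins within a stop-bounded segment (maximal, non-nested)
  o2 <- find_orfs("ATGATGAAATAG", min_len = 6)
  expect_equal(nrow(o2), 1)
  expect_equal(o2$start, 0)

  # reverse-complement symmetry: + ORFs of s map to - ORFs of revcomp(s)
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  a <- find_orfs(s, min_len = 30)
  b <- find_orfs(rc, min_len = 30)
  L <- nchar(s)
  mapped <- data.frame(start = L - b$end, end = L - b$start,
                       strand = ifelse(b$strand == "+", "-", "+"),
                       stringsAsFactors = FALSE)
  mapped <- mapped[order(mapped$start, mapped$end), ]
  rownames(mapped) <- NULL
  expect_equal(a, mapped)
})

test_that("codon_counts tallies codons over ORFs", {
  cc <- codon_counts("ATGAAATAA", min_len = 9)
  expect_equal(cc[["ATG"]], 1L)
  expect_equal(cc[["AAA"]], 1L)
  expect_equal(cc[["TAA"]], 1L)
  expect_length(codon_counts("CCCCCC"), 0)
})

test_that("feature_matrix flags invalid rows and fixes column order", {
  fm <- feature_matrix(c("ACGTACGTAC", "NNNNNNNN", "GGGGCCCCGG"), kind = "kmer", k = 2)
  expect_identical(attr(fm, "valid"), c(TRUE, FALSE, TRUE))
  expect_identical(colnames(fm), sort(colnames(fm)))
  expect_equal(rowSums(fm[attr(fm, "valid"), ]), c(1, 1), ignore_attr = TRUE)

  gm <- feature_matrix(c("ACGT", "NNNN"), kind = "gc")
  expect_identical(attr(gm, "valid"), c(TRUE, FALSE))
  expect_equal(gm[1, "GC"], 0.5, ignore_attr = TRUE)
})

test_that("embed_2d separates compositionally distinct genomes", {
  fa <- sample_fragments(fx$target, 25, seed = 21, prefix = "a")$contigs
  fb <- sample_fragments(fx$contam1, 25, seed = 22, prefix = "b")$contigs
  frags <- rbind(cbind(fragment_contigs(fa, 1000), dataset = "sample"),
                 cbind(fragment_contigs(fb, 1000), dataset = "control"))
  fm <- feature_matrix(frags$sequence, kind = "kmer", k = 4)
  pts <- embed_2d(fm, tags = frags$dataset,
                  parent_id = frags$parent_id, index = frags$index)
  a <- pts[pts$dataset == "sample", ]
  b <- pts[pts$dataset == "control", ]
  centroid_gap <- abs(mean(a$x) - mean(b$x))
  expect_gt(centroid_gap, max(sd(a$x), sd(b$x)))
})

test_that("embed_2d is deterministic, centered, and row-order invariant", {
  set.seed(23)
  X <- matrix(runif(40 * 6), 40, 6)
  colnames(X) <- paste0("f", 1:6)
  p1 <- embed_2d(X)

  # duplicating every row leaves the axes unchanged
  p2 <- embed_2d(rbind(X, X))
  expect_equal(attr(p1, "rotation"), attr(p2, "rotation"), tolerance = 1e-8)

  # permuting rows permutes the embedding identically
  perm <- sample(nrow(X))
  p3 <- embed_2d(X[perm, ])
  expect_equal(p3$x, p1$x[perm], tolerance = 1e-10)
  expect_equal(p3$y, p1$y[perm], tolerance = 1e-10)

  # the column-mean row projects to the origin
  at_mean <- sagclean:::project_features(rbind(colMeans(X)),
                                         attr(p1, "center"), attr(p1, "rotation"))
  expect_equal(as.numeric(at_mean), c(0, 0), tolerance = 1e-12)

  # sign convention: the largest-magnitude loading of each axis is positive
  rot <- attr(p1, "rotation")
  for (j in 1:2) expect_gt(rot[which.max(abs(rot[, j])), j], 0)
})

test_that("embed_2d rejects degenerate feature matrices", {
  X <- cbind(a = rep(1, 5), b = rep(2, 5)) + matrix(0, 5, 2)
  expect_error(embed_2d(X), "rank")
  expect_error(embed_2d(matrix(runif(4), 2, 2)), ">= 3 valid fragments")
  expect_error(embed_2d(matrix(runif(5), 5, 1)), "feature_kind")
})
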