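# Simulated-SAG benchmark generator. Datasets emulate the standard design:
# 1000 fragments per dataset, fragment lengths ~ Normal(3000, 500) bp,
# target and contaminant fragments mixed at graded proportions with the
# contaminant share split 3:1 between two species.

#' Mixing design for a simulated SAG dataset
#'
#' Given a total fragment count and a contamination rate, computes the
#' per-class counts: `round(total * (1 - rate))` target fragments, and the
#' contaminant remainder split among contaminant species (3:1 over two
#' species by default). Counts always sum to `total`.
#'
#' @param total Total fragments in the dataset (default 1000).
#' @param rate Contamination rate in `[0, 1]`.
#' @param split Proportions over contaminant species (default `c(0.75, 0.25)`).
#' @param species Contaminant species names (default `contaminant1`, ...).
#' @return Object of class `mix_design`: list with `total`, `rate`,
#'   `target_count`, named `contaminant_counts`, `split`.
#' @export
#' @examples
#' mix_design(1000, 0.30)$contaminant_counts # 225 75
mix_design <- function(total = 1000, rate, split = c(0.75, 0.25),
                       species = paste0("contaminant", seq_along(split))) {
  if (!is_count(total, min = 1)) stopf("total must be a positive integer")
  if (!is_fraction(rate)) stopf("rate must be in [0, 1]")
  if (any(split < 0) || abs(sum(split) - 1) > 1e-9) {
    stopf("split must be non-negative proportions summing to 1")
  }
  if (length(species) != length(split)) stopf("one species name per split share")
  target_count <- round(total * (1 - rate))
  cont_total <- total - target_count
  counts <- round(cont_total * split)
  counts[1] <- cont_total - sum(counts[-1]) # guarantee the counts sum to total
  if (any(counts < 0)) stopf("split rounding produced a negative count")
  structure(list(total = as.integer(total), rate = rate,
                 target_count = as.integer(target_count),
                 contaminant_counts = setNames(as.integer(counts), species),
                 split = split),
            class = "mix_design")
}

#' Sample fragments from a genome
#'
#' Draws `n` fragments at uniformly random positions on uniformly chosen
#' records. Fragment lengths are drawn from Normal(`mean_len`, `sd_len`),
#' rounded, and redrawn until they fall in `[1000, record length]` so that
#' every fragment survives downstream 1000 bp windowing.
#'
#' @param genome Named character vector of genome records (or FASTA path).
#'   Records shorter than 1000 bp are skipped with a warning; every usable
#'   record must be at least `mean_len` long.
#' @param n Number of fragments.
#' @param mean_len,sd_len Fragment length distribution in bp (defaults
#'   3000 and 500, the standard benchmark setting).
#' @param seed RNG seed for reproducibility.
#' @param prefix Fragment id prefix (default `"frag"`).
#' @return List with `contigs` (named character vector, ids
#'   `<prefix>_00001`, ...) and `info` (data frame: `id`, `record`,
#'   `start` 0-based, `length`).
#' @export
sample_fragments <- function(genome, n, mean_len = 3000, sd_len = 500,
                             seed = NULL, prefix = "frag") {
  genome <- as_contigs(genome)
  if (!is_count(n)) stopf("n must be a non-negative integer")
  lens <- nchar(genome)
  short <- lens < 1000
  if (any(short)) {
    warning(sprintf("skipping %d record(s) shorter than 1000 bp", sum(short)))
    genome <- genome[!short]; lens <- lens[!short]
  }
  if (length(genome) == 0) stopf("no usable genome records (all shorter than 1000 bp)")
  if (any(lens < mean_len)) stopf("every usable record must be at least mean_len bp")
  if (n == 0) {
    return(list(contigs = setNames(character(0), character(0)),
                info = data.frame(id = character(0), record = character(0),
                                  start = integer(0), length = integer(0),
                                  stringsAsFactors = FALSE)))
  }
  with_seed(seed, {
    rec <- sample.int(length(genome), n, replace = TRUE)
    frag_len <- integer(n)
    for (i in seq_len(n)) {
      repeat {
        l <- round(rnorm(1, mean_len, sd_len))
        if (l >= 1000 && l <= lens[rec[i]]) break
      }
      frag_len[i] <- as.integer(l)
    }
    start <- vapply(seq_len(n), function(i) {
      sample.int(lens[rec[i]] - frag_len[i] + 1L, 1L) - 1L
    }, integer(1))
    ids <- sprintf("%s_%05d", prefix, seq_len(n))
    contigs <- setNames(substring(genome[rec], start + 1L, start + frag_len), ids)
    list(contigs = contigs,
         info = data.frame(id = ids, record = names(genome)[rec],
                           start = start, length = frag_len,
                           stringsAsFactors = FALSE))
  })
}

#' Mix target and contaminant fragments into a simulated SAG dataset
#'
#' Draws exactly the per-class counts implied by the design, without
#' replacement, shuffles the result, and preserves true class labels.
#'
#' @param target_frags Named character vector of target fragments.
#' @param contaminant_frags Named list of named character vectors, one per
#'   contaminant species, in the design's species order.
#' @param design A [mix_design()].
#' @param seed RNG seed.
#' @param target_species Label recorded for target fragments
#'   (default `"target"`).
#' @return Object of class `sim_dataset`: list with `contigs` (named
#'   character vector), `labels` (data frame `id`, `species`, `class` with
#'   class in `target`/`non-target`), `design`, `seed`.
#' @export
mix_datasets <- function(target_frags, contaminant_frags, design, seed = NULL,
                         target_species = "target") {
  if (!inherits(design, "mix_design")) stopf("design must be a mix_design")
  species <- names(design$contaminant_counts)
  if (!is.list(contaminant_frags) || !all(species %in% names(contaminant_frags))) {
    stopf("contaminant_frags must be a named list covering species: %s",
          paste(species, collapse = ", "))
  }
  if (length(target_frags) < design$target_count) {
    stopf("insufficient target fragments: need %d, have %d",
          design$target_count, length(target_frags))
  }
  for (sp in species) {
    need <- design$contaminant_counts[[sp]]
    if (length(contaminant_frags[[sp]]) < need) {
      stopf("insufficient %s fragments: need %d, have %d",
            sp, need, length(contaminant_frags[[sp]]))
    }
  }
  with_seed(seed, {
    pick <- function(pool, n, sp_prefix) {
      if (n == 0) return(setNames(character(0), character(0)))
      sel <- pool[sample.int(length(pool), n)]
      # guard against id collisions across source pools
      names(sel) <- paste0(sp_prefix, "_", names(sel))
      sel
    }
    parts <- c(list(pick(target_frags, design$target_count, target_species)),
               lapply(species, function(sp) {
                 pick(contaminant_frags[[sp]], design$contaminant_counts[[sp]], sp)
               }))
    cls <- c(rep("target", design$target_count),
             rep("non-target", sum(design$contaminant_counts)))
    sp_lab <- c(rep(target_species, design$target_count),
                rep(species, design$contaminant_counts))
    contigs <- do.call(c, parts)
    ord <- sample.int(length(contigs))
    structure(list(contigs = contigs[ord],
                   labels = data.frame(id = names(contigs)[ord],
                                       species = sp_lab[ord], class = cls[ord],
                                       stringsAsFactors = FALSE),
                   design = design, seed = seed),
              class = "sim_dataset")
  })
}

#' Generate a synthetic genome from a random Markov chain
#'
#' Produces a download-free stand-in for a real bacterial genome: an
#' order-`order` Markov chain whose per-context transition probabilities
#' are softmax-perturbed away from uniform. `divergence` scales the
#' perturbation, so two genomes generated with different seeds and
#' `divergence > 0` have distinct k-mer compositions and are separable in
#' the composition embedding; `divergence = 0` approaches a uniform random
#' sequence.
#'
#' @param length Genome length in bp (minimum 10000).
#' @param order Markov order (default 2).
#' @param divergence Non-negative scale of compositional bias (default 0.5).
#' @param seed RNG seed; the same seed and parameters give the identical
#'   genome.
#' @return A single DNA string (unnamed character scalar).
#' @export
synthetic_genome <- function(length, order = 2, divergence = 0.5, seed = NULL) {
  if (!is_count(length, min = 10000)) stopf("length must be an integer >= 10000")
  if (!is_count(order)) stopf("order must be a non-negative integer")
  if (!is.numeric(divergence) || divergence < 0) stopf("divergence must be >= 0")
  bases <- c("A", "C", "G", "T")
  n_ctx <- 4^order
  with_seed(seed, {
    logits <- matrix(rnorm(n_ctx * 4), n_ctx, 4) * divergence
    prob <- exp(logits)
    prob <- prob / rowSums(prob)
    cum <- t(apply(prob, 1, cumsum))
    idx <- integer(length)
    # seed the context with uniform bases
    if (order > 0) idx[seq_len(order)] <- sample.int(4, order, replace = TRUE)
    ctx <- 0L
    if (order > 0) for (b in idx[seq_len(order)]) ctx <- (ctx * 4L + (b - 1L)) %% n_ctx
    u <- runif(length)
    start <- order + 1L
    if (start <= length) {
      for (i in start:length) {
        p <- cum[ctx + 1L, ]
        b <- 1L + (u[i] > p[1L]) + (u[i] > p[2L]) + (u[i] > p[3L])
        idx[i] <- b
        ctx <- (ctx * 4L + (b - 1L)) %% n_ctx
      }
    }
    paste(bases[idx], collapse = "")
  })
}

#' Write a simulated dataset to disk
#'
#' Emits the dataset FASTA, a label TSV (`id`, `species`, `class`) and a
#' plain-text manifest recording the design and seed, so a run can be
#' reproduced exactly.
#'
#' @param dataset A `sim_dataset` from [mix_datasets()].
#' @param fasta_path,labels_path,manifest_path Output paths; `NULL` skips.
#' @return Invisibly, the dataset.
#' @export
write_dataset <- function(dataset, fasta_path, labels_path,
                          manifest_path = NULL) {
  if (!inherits(dataset, "sim_dataset")) stopf("dataset must be a sim_dataset")
  write_fasta(dataset$contigs, fasta_path)
  write.table(dataset$labels, labels_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(manifest_path)) {
    d <- dataset$design
    writeLines(c(
      sprintf("total = %d", d$total),
      sprintf("contamination_rate = %g", d$rate),
      sprintf("target_count = %d", d$target_count),
      sprintf("contaminant_counts = %s",
              paste(sprintf("%s:%d", names(d$contaminant_counts),
                            d$contaminant_counts), collapse = ", ")),
      sprintf("seed = %s", dataset$seed %||% "NULL")
    ), manifest_path)
  }
  invisible(dataset)
}
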