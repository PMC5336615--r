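# Evaluation metrics for the benchmark: correlation between density grids,
# ROC/AUC of confidence scores, sensitivity/specificity at a threshold, and
# the full contamination-rate sweep.

as_class_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  labels <- as.character(labels)
  ok <- labels %in% c("target", "non-target")
  if (any(!ok)) {
    stopf("labels must be logical or 'target'/'non-target'; got: %s",
          paste(unique(labels[!ok]), collapse = ", "))
  }
  labels == "target"
}

#' Pearson correlation between two density grids
#'
#' Correlation over all `M^2` block pairs, flattened in fixed order; the
#' standard summary of how well a recovered distribution matches a
#' reference distribution.
#'
#' @param A,B `density_grid` objects with the same spec.
#' @return Pearson r, or `NA` (with a warning) when either grid has zero
#'   variance.
#' @export
grid_correlation <- function(A, B) {
  grids_checked(A, B)
  a <- as.vector(A$mass); b <- as.vector(B$mass)
  if (sd(a) == 0 || sd(b) == 0) {
    warning("zero variance in a density grid; correlation undefined")
    return(NA_real_)
  }
  cor(a, b)
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation with ties counted 1/2, which equals the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric confidence scores.
#' @param labels Logical (`TRUE` = target) or character
#'   (`"target"`/`"non-target"`), one per score.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  lab <- as_class_labels(labels)
  if (length(scores) != length(lab)) stopf("scores and labels differ in length")
  keep <- !is.na(scores)
  scores <- scores[keep]; lab <- lab[keep]
  n1 <- sum(lab); n0 <- sum(!lab)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present to compute AUC")
  r <- rank(scores) # average ranks: the 1/2 tie convention
  (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity and specificity of a confidence threshold
#'
#' Contigs with `score > threshold` are kept. Sensitivity is the fraction
#' of target contigs retained; specificity is the fraction of non-target
#' contigs discarded (note: *discarded*, the decontamination convention --
#' a discarded non-target is a success).
#'
#' @inheritParams roc_auc
#' @param threshold Confidence threshold in `[0, 1]`.
#' @return Named vector `c(sensitivity, specificity)`.
#' @export
sens_spec <- function(scores, labels, threshold = 0.7) {
  lab <- as_class_labels(labels)
  if (length(scores) != length(lab)) stopf("scores and labels differ in length")
  if (!is_fraction(threshold)) stopf("threshold must be in [0, 1]")
  keep <- !is.na(scores)
  if (any(!keep)) {
    warning(sprintf("dropping %d item(s) with undefined scores", sum(!keep)))
    scores <- scores[keep]; lab <- lab[keep]
  }
  if (!any(lab) || all(lab)) stopf("both classes must be present")
  kept <- scores > threshold
  c(sensitivity = sum(kept & lab) / sum(lab),
    specificity = sum(!kept & !lab) / sum(!lab))
}

#' Sweep contamination rates and measure recovery end to end
#'
#' For each rate and replicate, simulates a SAG dataset at that
#' contamination rate plus an independent pure-target dataset (the truth
#' reference) and pure-contaminant dataset (the no-template control),
#' runs the full decontamination pipeline, and records the estimated
#' contamination proportion, the Pearson correlation of the recovered
#' target density with the pure-target density, the AUC of the confidence
#' scores against the true labels, and sensitivity/specificity at
#' `threshold`.
#'
#' @param target_genome Named character vector (or FASTA path) of the
#'   target genome.
#' @param contaminant_genomes Named list of genomes, one per contaminant
#'   species.
#' @param rates Contamination rates to simulate (>= 2 values).
#' @param replicates Replicates per rate (default 1).
#' @param total Fragments per dataset (default 1000).
#' @param split Contaminant split proportions (default `c(0.75, 0.25)`).
#' @param seed Base RNG seed; every draw derives from it.
#' @param threshold Confidence threshold for sensitivity/specificity.
#' @param mean_len,sd_len Simulated fragment length distribution (bp).
#' @param frag_len,k,M,margin Pipeline parameters, as in [decontaminate()].
#' @return Object of class `contamination_sweep`: list with `results` (data
#'   frame: `replicate`, `rate`, `p_n`, `r_dist`, `auc`, `sensitivity`,
#'   `specificity`) and `pearson_r`, the correlation between true and
#'   estimated contamination across all rows.
#' @export
contamination_sweep <- function(target_genome, contaminant_genomes,
                                rates = seq(0, 1, by = 0.1), replicates = 1,
                                total = 1000, split = c(0.75, 0.25),
                                seed = NULL, threshold = 0.7,
                                mean_len = 3000, sd_len = 500,
                                frag_len = 1000, k = 4, M = 50, margin = 0.05) {
  if (length(unique(rates)) < 2) stopf("need >= 2 distinct rates for a sweep")
  if (!all(vapply(rates, is_fraction, logical(1)))) stopf("rates must lie in [0, 1]")
  target_genome <- as_contigs(target_genome)
  contaminant_genomes <- lapply(contaminant_genomes, as_contigs)
  species <- names(contaminant_genomes)
  if (is.null(species) || any(!nzchar(species))) {
    stopf("contaminant_genomes must be a named list")
  }
  counter <- 0L
  next_seed <- function() { counter <<- counter + 1L; derive_seed(seed, counter) }
  draw_dataset <- function(rate) {
    design <- mix_design(total, rate, split = split, species = species)
    tf <- sample_fragments(target_genome, design$target_count,
                           mean_len, sd_len, seed = next_seed(), prefix = "t")
    cf <- lapply(seq_along(species), function(s) {
      sample_fragments(contaminant_genomes[[s]], design$contaminant_counts[[s]],
                       mean_len, sd_len, seed = next_seed(),
                       prefix = sprintf("c%d", s))
    })
    names(cf) <- species
    mix_datasets(tf$contigs, lapply(cf, `[[`, "contigs"), design,
                 seed = next_seed())
  }
  rows <- list()
  for (rep_i in seq_len(replicates)) {
    truth <- draw_dataset(0)
    control <- draw_dataset(1)
    for (rate in rates) {
      ds <- draw_dataset(rate)
      fit <- tryCatch(
        decontaminate(ds$contigs, control$contigs, reference = truth$contigs,
                      frag_len = frag_len, min_len = min(500, frag_len), k = k,
                      M = M, margin = margin),
        sagclean_pure_contamination = function(c) c
      )
      if (inherits(fit, "condition")) {
        rows[[length(rows) + 1L]] <- data.frame(
          replicate = rep_i, rate = rate, p_n = fit$p_n, r_dist = NA_real_,
          auc = NA_real_, sensitivity = NA_real_, specificity = NA_real_)
        next
      }
      ref_pts <- fit$points[fit$points$dataset == "reference", , drop = FALSE]
      D_truth <- density_grid(ref_pts, fit$grid)
      r_dist <- grid_correlation(fit$D_t, D_truth)
      sc <- fit$scores
      lab <- ds$labels$class[match(sc$contig_id, ds$labels$id)]
      two_class <- length(unique(lab)) == 2
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = rep_i, rate = rate, p_n = fit$p_n, r_dist = r_dist,
        auc = if (two_class) roc_auc(sc$confidence, lab) else NA_real_,
        sensitivity = if (two_class) sens_spec(sc$confidence, lab, threshold)[["sensitivity"]] else NA_real_,
        specificity = if (two_class) sens_spec(sc$confidence, lab, threshold)[["specificity"]] else NA_real_)
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(list(results = results,
                 pearson_r = cor(results$rate, results$p_n),
                 threshold = threshold, total = total, seed = seed),
            class = "contamination_sweep")
}

#' @export
print.contamination_sweep <- function(x, ...) {
  cat(sprintf("Contamination sweep: %d runs, %d fragments/dataset\n",
              nrow(x$results), x$total))
  cat(sprintf("  Pearson r (estimated vs true contamination): %.4f\n", x$pearson_r))
  agg <- stats::aggregate(cbind(p_n, r_dist, auc) ~ rate, data = x$results,
                          FUN = mean, na.action = stats::na.pass)
  print(round(agg, 4), row.names = FALSE)
  invisible(x)
}
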