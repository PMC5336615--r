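# Core of the method: the sample density is modelled as a two-component
# mixture f_s = p_t * f_t + p_n * f_n, where f_n is estimated from the
# no-template control. The contamination proportion p_n is estimated from
# grid blocks where the control density dominates, the target component is
# recovered by subtraction, and per-block posteriors give contig scores.

grids_checked <- function(D_s, D_n) {
  if (!inherits(D_s, "density_grid") || !inherits(D_n, "density_grid")) {
    stopf("inputs must be density_grid objects")
  }
  if (!same_spec(D_s$spec, D_n$spec)) stopf("density grids have mismatched grid specs")
  invisible(TRUE)
}

#' Estimate the contamination proportion from sample and control densities
#'
#' Over the blocks where the control (non-target) density is at least the
#' sample density, the sample mass can only have come from the contaminant
#' component; the ratio of summed sample mass to summed control mass over
#' those blocks estimates the contaminant proportion `p_n`. The comparison
#' is non-strict so that a sample identical to the control yields
#' `p_n = 1`. The ratio is clamped to `[0, 1]`; an empty qualifying set
#' returns 0.
#'
#' @param D_s Sample density grid.
#' @param D_n Control (non-target) density grid with the same spec.
#' @return Estimated contaminant proportion `p_n` in `[0, 1]`.
#' @export
estimate_contamination <- function(D_s, D_n) {
  grids_checked(D_s, D_n)
  q <- D_n$mass >= D_s$mass
  denom <- sum(D_n$mass[q])
  if (denom == 0) return(0)
  min(1, max(0, sum(D_s$mass[q]) / denom))
}

#' Recover the target density by background subtraction
#'
#' Applies `D_t = (D_s - p_n * D_n) / p_t` per block, then clips negative
#' entries (possible because the raw subtraction is unconstrained) to zero
#' and renormalizes to sum 1 -- a probability mass function must be
#' non-negative.
#'
#' @param D_s Sample density grid.
#' @param D_n Control density grid with the same spec.
#' @param p_n Contaminant proportion in `[0, 1)`.
#' @return A `density_grid` for the estimated target distribution, with a
#'   `clipped` attribute marking blocks where clipping fired.
#' @export
subtract_distribution <- function(D_s, D_n, p_n) {
  grids_checked(D_s, D_n)
  if (!is_fraction(p_n)) stopf("p_n must be in [0, 1]")
  if (p_n >= 1) {
    stopf("p_n = 1: sample indistinguishable from control; no target mass recoverable")
  }
  p_t <- 1 - p_n
  raw <- (D_s$mass - p_n * D_n$mass) / p_t
  clipped <- raw < 0
  raw[clipped] <- 0
  tot <- sum(raw)
  if (tot == 0) stopf("subtraction left no target mass")
  structure(list(spec = D_s$spec, mass = raw / tot, n = D_s$n, h = D_s$h,
                 sd = D_s$sd, clipped = clipped),
            class = "density_grid")
}

#' Per-block posterior confidence map
#'
#' `c(x) = p_t f_t(x) / (p_t f_t(x) + p_n f_n(x))`: the posterior
#' probability that a fragment at `x` originates from the target component.
#' Blocks where both densities vanish carry no likelihood evidence and are
#' assigned the prior `p_t`.
#'
#' @param D_t Target density grid (from [subtract_distribution()]).
#' @param D_n Control density grid with the same spec.
#' @param p_t,p_n Mixture proportions; must sum to 1.
#' @return M x M matrix of confidences in `[0, 1]`.
#' @export
confidence_map <- function(D_t, D_n, p_t, p_n) {
  grids_checked(D_t, D_n)
  if (!is_fraction(p_t) || !is_fraction(p_n) || abs(p_t + p_n - 1) > 1e-12) {
    stopf("p_t and p_n must be fractions summing to 1")
  }
  num <- p_t * D_t$mass
  den <- num + p_n * D_n$mass
  cmap <- ifelse(den > 0, num / den, p_t)
  pmin(pmax(cmap, 0), 1) # cmap first so the matrix dim survives
}

#' Score contigs by mean fragment confidence
#'
#' Each embedded fragment receives the confidence of its enclosing grid
#' block; a contig's score `c_i` is the arithmetic mean over its fragments.
#' Contigs whose fragments were all invalid at the composition stage are
#' reported with `NA` confidence. Fragments falling outside the grid are
#' assigned the nearest boundary block (with a message).
#'
#' @param points Embedded sample fragments (rows of [embed_2d()] output
#'   with `parent_id` set).
#' @param model A fitted [decontaminate()] model, or any list with
#'   elements `grid` (a [grid_spec()]) and `conf_map`.
#' @param all_parents Optional character vector of every contig id that
#'   should appear in the table (contigs with no valid fragment get `NA`).
#' @return Data frame of class `score_table`: `contig_id`, `n_fragments`,
#'   `confidence` (0--1), `confidence_pct`.
#' @export
score_contigs <- function(points, model, all_parents = NULL) {
  spec <- model$grid
  cmap <- model$conf_map
  if (is.null(spec) || is.null(cmap)) stopf("model must carry `grid` and `conf_map`")
  if (nrow(points) > 0 && any(is.na(points$parent_id))) {
    stopf("points must carry parent_id for contig scoring")
  }
  if (nrow(points) > 0) {
    bi <- block_index(spec, points$x, points$y)
    if (bi$n_outside > 0) {
      message(sprintf("%d fragment(s) outside grid bounds assigned to boundary blocks",
                      bi$n_outside))
    }
    frag_conf <- cmap[cbind(bi$i, bi$j)]
    ids <- unique(points$parent_id)
    conf <- tapply(frag_conf, factor(points$parent_id, levels = ids), mean)
    nfr <- tapply(frag_conf, factor(points$parent_id, levels = ids), length)
    tab <- data.frame(contig_id = ids, n_fragments = as.integer(nfr),
                      confidence = as.numeric(conf), stringsAsFactors = FALSE)
  } else {
    tab <- data.frame(contig_id = character(0), n_fragments = integer(0),
                      confidence = numeric(0), stringsAsFactors = FALSE)
  }
  if (!is.null(all_parents)) {
    missing <- setdiff(all_parents, tab$contig_id)
    if (length(missing)) {
      tab <- rbind(tab, data.frame(contig_id = missing, n_fragments = 0L,
                                   confidence = NA_real_, stringsAsFactors = FALSE))
    }
    tab <- tab[match(all_parents, tab$contig_id), , drop = FALSE]
  }
  tab$confidence_pct <- 100 * tab$confidence
  rownames(tab) <- NULL
  class(tab) <- c("score_table", "data.frame")
  tab
}

#' Partition contigs by confidence threshold
#'
#' Keeps contigs with confidence strictly greater than `threshold`
#' (matching the usual "scores higher than 70" usage on the 0--100 scale).
#' Contigs with `NA` confidence are discarded.
#'
#' @param table A `score_table`.
#' @param contigs Named character vector of the scored contigs.
#' @param threshold Confidence threshold in `[0, 1]` (default 0.7).
#' @return List with elements `kept` and `discarded` (named character
#'   vectors; an exhaustive, disjoint partition of `contigs`).
#' @export
filter_by_confidence <- function(table, contigs, threshold = 0.7) {
  if (!is_fraction(threshold)) stopf("threshold must be in [0, 1]")
  contigs <- as_contigs(contigs)
  conf <- table$confidence[match(names(contigs), table$contig_id)]
  keep <- !is.na(conf) & conf > threshold
  list(kept = contigs[keep], discarded = contigs[!keep])
}

#' Fit a composition-based decontamination model
#'
#' The top-level fitting function. Both sequence sets are length-filtered
#' and fragmented; fragments of all datasets are embedded together into a
#' shared 2-D composition space; sample and control densities are estimated
#' on a common grid; the contamination proportion `p_n` is estimated, the
#' target density recovered by subtraction, and every sample contig scored
#' with the posterior probability of target origin.
#'
#' @param sample Sample SAG contigs: a named character vector or FASTA path.
#' @param control No-template-control (non-target) contigs, same forms.
#' @param reference Optional reference contigs (e.g. a related genome);
#'   included in the pooled embedding and useful for plots, not used in the
#'   mixture fit.
#' @param frag_len Fragment window length in bp (default 1000).
#' @param min_len Minimum contig length retained (default 500).
#' @param k Word length for `feature_kind = "kmer"` (default 4).
#' @param feature_kind Composition feature space: `"kmer"`, `"gc"` or
#'   `"codon"`.
#' @param M Grid blocks per axis (default 50).
#' @param margin Fractional grid margin (default 0.05).
#' @return Object of class `sag_decontam`; see [predict.sag_decontam()],
#'   [plot.sag_decontam()], `coef`, `summary`, `fitted`, `residuals`.
#'   If the sample is indistinguishable from the control (`p_n = 1`) the
#'   fit aborts with a condition of class `sagclean_pure_contamination`
#'   carrying the estimate.
#' @export
#' @examples
#' tg <- synthetic_genome(60000, divergence = 0.8, seed = 1)
#' cg <- synthetic_genome(60000, divergence = 0.8, seed = 2)
#' smp <- sample_fragments(c(target = tg), 60, seed = 3)$contigs
#' ctl <- sample_fragments(c(contam = cg), 60, seed = 4)$contigs
#' fit <- decontaminate(smp, ctl, M = 30)
#' coef(fit)
decontaminate <- function(sample, control, reference = NULL,
                          frag_len = 1000, min_len = 500, k = 4,
                          feature_kind = c("kmer", "gc", "codon"),
                          M = 50, margin = 0.05) {
  feature_kind <- match.arg(feature_kind)
  cl <- match.call()

  smp <- filter_min_length(as_contigs(sample), min_len)
  ctl <- filter_min_length(as_contigs(control), min_len)
  if (length(smp) == 0) stopf("no sample contigs pass the %d bp length filter", min_len)
  if (length(ctl) == 0) stopf("no control contigs pass the %d bp length filter", min_len)
  ref <- if (!is.null(reference)) filter_min_length(as_contigs(reference), min_len)

  frags <- rbind(
    cbind(fragment_contigs(smp, frag_len), dataset = "sample"),
    cbind(fragment_contigs(ctl, frag_len), dataset = "control"),
    if (!is.null(ref) && length(ref))
      cbind(fragment_contigs(ref, frag_len), dataset = "reference")
  )
  fm <- feature_matrix(frags$sequence, kind = feature_kind, k = k)
  pts <- embed_2d(fm, tags = frags$dataset,
                  parent_id = frags$parent_id, index = frags$index)
  spec <- shared_grid(pts, M = M, margin = margin)

  sp <- pts[pts$dataset == "sample", , drop = FALSE]
  cp <- pts[pts$dataset == "control", , drop = FALSE]
  if (nrow(sp) == 0) stopf("no valid sample fragments after composition filtering")
  if (nrow(cp) == 0) stopf("no valid control fragments after composition filtering")
  D_s <- density_grid(sp, spec)
  D_n <- density_grid(cp, spec)
  p_n <- estimate_contamination(D_s, D_n)
  # identical sample/control grids give p_n = 1 only up to summation roundoff
  if (p_n >= 1 - 1e-9) {
    cond <- structure(
      class = c("sagclean_pure_contamination", "error", "condition"),
      list(message = paste0(
             "estimated p_n = 1: sample indistinguishable from control; ",
             "no target mass recoverable"),
           call = cl, p_n = p_n))
    stop(cond)
  }
  p_t <- 1 - p_n
  D_t <- subtract_distribution(D_s, D_n, p_n)
  cmap <- confidence_map(D_t, D_n, p_t, p_n)

  model <- structure(list(
    call = cl,
    feature_kind = feature_kind, k = k, frag_len = frag_len, min_len = min_len,
    center = attr(pts, "center"), rotation = attr(pts, "rotation"),
    points = pts, grid = spec,
    D_s = D_s, D_n = D_n, D_t = D_t,
    p_n = p_n, p_t = p_t, conf_map = cmap,
    n_contigs = c(sample = length(smp), control = length(ctl),
                  reference = length(ref %||% character(0)))
  ), class = "sag_decontam")
  model$scores <- score_contigs(sp, model, all_parents = names(smp))
  model
}

#' @export
print.sag_decontam <- function(x, ...) {
  cat("Composition-based SAG decontamination model\n")
  cat(sprintf("  feature space : %s%s, 2 principal components\n", x$feature_kind,
              if (x$feature_kind == "kmer") sprintf(" (k = %d)", x$k) else ""))
  cat(sprintf("  fragments     : sample %d, control %d%s (window %d bp)\n",
              x$D_s$n, x$D_n$n,
              if (x$n_contigs[["reference"]] > 0)
                sprintf(", reference %d", sum(x$points$dataset == "reference")) else "",
              x$frag_len))
  cat(sprintf("  grid          : %d x %d blocks\n", x$grid$M, x$grid$M))
  cat(sprintf("  contamination : p_n = %.3f (target proportion p_t = %.3f)\n",
              x$p_n, x$p_t))
  ok <- !is.na(x$scores$confidence)
  cat(sprintf("  contig scores : %d contigs, median confidence %.3f\n",
              nrow(x$scores), stats::median(x$scores$confidence[ok])))
  invisible(x)
}

#' @export
summary.sag_decontam <- function(object, thresholds = c(0.5, 0.7, 0.9), ...) {
  conf <- object$scores$confidence
  ok <- !is.na(conf)
  out <- list(
    model = object,
    p_n = object$p_n, p_t = object$p_t,
    bandwidth = c(sample = object$D_s$h, control = object$D_n$h),
    grid = object$grid,
    n_clipped = sum(object$D_t$clipped),
    score_quantiles = stats::quantile(conf[ok], c(0, 0.25, 0.5, 0.75, 1)),
    n_unscored = sum(!ok),
    above = vapply(thresholds, function(t) sum(conf[ok] > t), integer(1)),
    thresholds = thresholds
  )
  class(out) <- "summary.sag_decontam"
  out
}

#' @export
print.summary.sag_decontam <- function(x, ...) {
  print(x$model)
  cat(sprintf("  bandwidths    : sample h = %.4f, control h = %.4f (Scott's rule)\n",
              x$bandwidth[["sample"]], x$bandwidth[["control"]]))
  cat(sprintf("  grid bounds   : x [%.3f, %.3f], y [%.3f, %.3f]\n",
              x$grid$x_min, x$grid$x_max, x$grid$y_min, x$grid$y_max))
  cat(sprintf("  subtraction   : %d block(s) clipped at zero\n", x$n_clipped))
  cat("  score quartiles:\n")
  print(round(x$score_quantiles, 4))
  for (i in seq_along(x$thresholds)) {
    cat(sprintf("  contigs with confidence > %.2f : %d\n", x$thresholds[i], x$above[i]))
  }
  if (x$n_unscored > 0) cat(sprintf("  contigs without valid fragments: %d\n", x$n_unscored))
  invisible(x)
}

#' @export
coef.sag_decontam <- function(object, ...) {
  c(p_t = object$p_t, p_n = object$p_n)
}

#' Score contigs with a fitted decontamination model
#'
#' With `newdata = NULL`, returns the fitted per-contig score table. With
#' new contigs, fragments them, computes the model's composition features,
#' projects them into the fitted embedding and scores them against the
#' fitted confidence map.
#'
#' @param object A `sag_decontam` model.
#' @param newdata Optional contigs (named character vector or FASTA path).
#' @param type `"contig"` for a per-contig `score_table` (default) or
#'   `"fragment"` for per-fragment confidences.
#' @param ... Unused.
#' @return A `score_table`, or a per-fragment data frame.
#' @export
predict.sag_decontam <- function(object, newdata = NULL,
                                 type = c("contig", "fragment"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    pts <- object$points[object$points$dataset == "sample", , drop = FALSE]
    if (type == "contig") return(object$scores)
  } else {
    ctg <- as_contigs(newdata)
    frags <- fragment_contigs(ctg, object$frag_len)
    fm <- feature_matrix(frags$sequence, kind = object$feature_kind, k = object$k)
    valid <- attr(fm, "valid")
    sc <- project_features(fm[valid, , drop = FALSE], object$center, object$rotation)
    pts <- data.frame(x = sc[, 1], y = sc[, 2],
                      parent_id = frags$parent_id[valid],
                      index = frags$index[valid], stringsAsFactors = FALSE)
    if (type == "contig") {
      return(score_contigs(pts, object, all_parents = names(ctg)))
    }
  }
  bi <- block_index(object$grid, pts$x, pts$y)
  data.frame(parent_id = pts$parent_id, index = pts$index,
             x = pts$x, y = pts$y,
             confidence = object$conf_map[cbind(bi$i, bi$j)],
             stringsAsFactors = FALSE)
}

#' @export
fitted.sag_decontam <- function(object, ...) {
  object$p_t * object$D_t$mass + object$p_n * object$D_n$mass
}

#' @export
residuals.sag_decontam <- function(object, ...) {
  object$D_s$mass - fitted(object)
}

#' Plot a fitted decontamination model
#'
#' `which = "scatter"` draws the shared composition scatterplot (control
#' red, sample grey, reference blue); `"confidence"` images the per-block
#' posterior confidence map; `"target"` images the recovered target
#' density; `"sample"` the raw sample density.
#'
#' @param x A `sag_decontam` model.
#' @param which One of `"scatter"`, `"confidence"`, `"target"`, `"sample"`.
#' @param ... Passed to the underlying base graphics call.
#' @return Invisibly, `x`.
#' @export
plot.sag_decontam <- function(x, which = c("scatter", "confidence", "target", "sample"),
                              ...) {
  which <- match.arg(which)
  cen <- grid_centers(x$grid)
  if (which == "scatter") {
    cols <- c(sample = grDevices::grey(0.3, alpha = 0.5),
              control = grDevices::rgb(0.8, 0.2, 0.2, 0.5),
              reference = grDevices::rgb(0.2, 0.3, 0.8, 0.5))
    ord <- order(match(x$points$dataset, c("control", "reference", "sample")))
    graphics::plot(x$points$x[ord], x$points$y[ord],
                   col = cols[x$points$dataset[ord]], pch = 16, cex = 0.4,
                   xlab = "PC1", ylab = "PC2",
                   main = "Fragments in composition space", ...)
    graphics::legend("topright", legend = names(cols)[c(TRUE, TRUE, x$n_contigs[["reference"]] > 0)],
                     col = cols[c(TRUE, TRUE, x$n_contigs[["reference"]] > 0)], pch = 16, bty = "n")
  } else {
    z <- switch(which, confidence = x$conf_map, target = x$D_t$mass,
                sample = x$D_s$mass)
    main <- switch(which, confidence = "Posterior confidence map",
                   target = "Estimated target density",
                   sample = "Sample density")
    graphics::image(cen$x, cen$y, z, xlab = "PC1", ylab = "PC2",
                    main = main, col = grDevices::hcl.colors(64, "viridis"), ...)
  }
  invisible(x)
}
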