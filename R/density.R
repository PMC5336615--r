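# Probability-mass grids over the 2-D embedding. A scatterplot region is
# divided into M x M equal blocks; Gaussian kernel density estimation is
# evaluated at block centers and globally normalized, so each grid is a
# probability mass function regardless of the kernel constants.

#' Grid specification for density estimation
#'
#' @param x_min,x_max,y_min,y_max Real bounds of the region.
#' @param M Blocks per axis (default 50).
#' @param sd Optional named per-axis standardization scale `c(x =, y =)`
#'   for kernel evaluation. When set (as [shared_grid()] does, from the
#'   pooled points), every density computed on this grid uses the same
#'   kernel metric, which keeps grids of different datasets comparable.
#' @return Object of class `grid_spec`.
#' @export
grid_spec <- function(x_min, x_max, y_min, y_max, M = 50, sd = NULL) {
  if (!is_count(M, min = 2)) stopf("M must be an integer >= 2")
  if (!(x_min < x_max) || !(y_min < y_max)) stopf("grid bounds must satisfy min < max")
  if (!is.null(sd) && (length(sd) != 2 || any(!is.finite(sd)) || any(sd <= 0))) {
    stopf("sd must be two positive finite values")
  }
  structure(list(M = as.integer(M), x_min = x_min, x_max = x_max,
                 y_min = y_min, y_max = y_max, sd = sd),
            class = "grid_spec")
}

# Block centers: bounds subdivided into M equal blocks per axis.
grid_centers <- function(spec) {
  wx <- (spec$x_max - spec$x_min) / spec$M
  wy <- (spec$y_max - spec$y_min) / spec$M
  list(x = spec$x_min + (seq_len(spec$M) - 0.5) * wx,
       y = spec$y_min + (seq_len(spec$M) - 0.5) * wy)
}

same_spec <- function(a, b, tol = 1e-9) {
  a$M == b$M &&
    abs(a$x_min - b$x_min) < tol && abs(a$x_max - b$x_max) < tol &&
    abs(a$y_min - b$y_min) < tol && abs(a$y_max - b$y_max) < tol
}

# Map points to enclosing block indices; out-of-bounds points are clamped to
# the nearest boundary block (and counted, so callers can log).
block_index <- function(spec, x, y) {
  wx <- (spec$x_max - spec$x_min) / spec$M
  wy <- (spec$y_max - spec$y_min) / spec$M
  i <- floor((x - spec$x_min) / wx) + 1
  j <- floor((y - spec$y_min) / wy) + 1
  out <- sum(x < spec$x_min | x > spec$x_max | y < spec$y_min | y > spec$y_max)
  list(i = pmin(spec$M, pmax(1L, as.integer(i))),
       j = pmin(spec$M, pmax(1L, as.integer(j))),
       n_outside = out)
}

#' Scott's-rule bandwidth
#'
#' `h = n^(-1/(d+4))`; for the 2-D composition scatterplot, `h = n^(-1/6)`.
#' Applied to axis-standardized coordinates (see [density_grid()]).
#'
#' @param n Number of points.
#' @param d Dimensionality (default 2).
#' @return Bandwidth `h`.
#' @export
#' @examples
#' scotts_bandwidth(64) # 0.5
scotts_bandwidth <- function(n, d = 2) {
  if (!is_count(n, min = 1)) stopf("n must be a positive integer")
  n^(-1 / (d + 4))
}

#' Shared grid bounds over one or more point sets
#'
#' Takes the joint min/max of all supplied point sets per axis and expands
#' by `margin` of the range on each side, so that sample, control and
#' reference densities are computed over the identical region. A zero-range
#' axis is expanded by a fixed 0.5 units each side. The pooled per-axis
#' standard deviations are stored in the spec so that every density on
#' this grid is smoothed on one common kernel metric.
#'
#' @param points An `embedded_points` data frame (or anything with `x`/`y`
#'   columns), or a list of them.
#' @param M Blocks per axis (default 50).
#' @param margin Fractional expansion per side (default 0.05).
#' @return A [grid_spec()].
#' @export
shared_grid <- function(points, M = 50, margin = 0.05) {
  if (is.data.frame(points)) points <- list(points)
  x <- unlist(lapply(points, function(p) p$x))
  y <- unlist(lapply(points, function(p) p$y))
  if (length(x) < 1) stopf("need at least one point")
  if (!is.numeric(margin) || margin < 0) stopf("margin must be >= 0")
  bounds <- function(v) {
    r <- range(v)
    if (diff(r) == 0) return(c(r[1] - 0.5, r[2] + 0.5))
    c(r[1] - margin * diff(r), r[2] + margin * diff(r))
  }
  bx <- bounds(x); by <- bounds(y)
  sx <- sd(x); sy <- sd(y)
  if (!is.finite(sx) || sx == 0) sx <- 1
  if (!is.finite(sy) || sy == 0) sy <- 1
  grid_spec(bx[1], bx[2], by[1], by[2], M = M, sd = c(x = sx, y = sy))
}

#' Kernel density estimate on a block grid
#'
#' Evaluates, at every block center, a separable product of univariate
#' Gaussian kernels over the two coordinate differences, with a single
#' Scott's-rule bandwidth applied to axis-standardized coordinates. The
#' standardization scale is the one recorded in the grid spec (the pooled
#' points' per-axis SD when the spec came from [shared_grid()]), so every
#' density on one grid shares one kernel metric; a spec without a scale
#' falls back to the point set's own SD, the scaling `gaussian_kde`-style
#' estimators apply through the data covariance. The full matrix is then
#' normalized to sum 1, giving a probability mass function over blocks;
#' kernel normalization constants cancel in that step.
#'
#' @param points Data frame with `x`, `y` columns (e.g. a subset of
#'   [embed_2d()] output).
#' @param spec A [grid_spec()]; use [shared_grid()] so that grids of
#'   different datasets are comparable.
#' @return Object of class `density_grid`: list with `spec`, `mass`
#'   (M x M matrix, rows index x-blocks, columns y-blocks, sums to 1),
#'   `n`, `h`, and the per-axis standardization `sd`.
#' @export
density_grid <- function(points, spec) {
  if (!inherits(spec, "grid_spec")) stopf("spec must be a grid_spec")
  x <- points$x; y <- points$y
  n <- length(x)
  if (n < 1) stopf("empty point set")
  if (any(!is.finite(x)) || any(!is.finite(y))) stopf("points must be finite")
  h <- scotts_bandwidth(n, d = 2)
  if (!is.null(spec$sd)) {
    sx <- spec$sd[["x"]]; sy <- spec$sd[["y"]]
  } else {
    sx <- sd(x); sy <- sd(y)
    if (!is.finite(sx) || sx == 0) sx <- 1
    if (!is.finite(sy) || sy == 0) sy <- 1
  }
  cen <- grid_centers(spec)
  Ax <- dnorm(outer(cen$x, x, "-") / (h * sx))
  Ay <- dnorm(outer(cen$y, y, "-") / (h * sy))
  raw <- (Ax %*% t(Ay)) / (n * h)
  mass <- raw / sum(raw)
  structure(list(spec = spec, mass = mass, n = n, h = h, sd = c(x = sx, y = sy)),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("Density grid: %d x %d blocks, %d points, h = %.4f\n",
              x$spec$M, x$spec$M, x$n, x$h))
  cat(sprintf("  x in [%.3f, %.3f], y in [%.3f, %.3f]\n",
              x$spec$x_min, x$spec$x_max, x$spec$y_min, x$spec$y_max))
  invisible(x)
}

#' Export a density grid (or any M x M matrix) as TSV
#'
#' @param grid A `density_grid` or numeric matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_grid_tsv <- function(grid, path) {
  m <- if (inherits(grid, "density_grid")) grid$mass else as.matrix(grid)
  write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
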