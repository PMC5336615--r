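# Independent brute-force oracles: literal, loop-based evaluations of the
# method's defining formulas, kept free of any package internals so they can
# check the vectorized implementations.

# KDE mass grid: D'_ij = (1/nh) sum_k K((x_ij - x_k)/h), with the product of
# univariate Gaussian kernels over the two standardized coordinate
# differences, then D = D' / sum(D').
oracle_density_mass <- function(px, py, spec) {
  n <- length(px)
  h <- n^(-1 / 6)
  if (!is.null(spec$sd)) {
    sx <- spec$sd[["x"]]; sy <- spec$sd[["y"]]
  } else {
    sx <- stats::sd(px); sy <- stats::sd(py)
    if (!is.finite(sx) || sx == 0) sx <- 1
    if (!is.finite(sy) || sy == 0) sy <- 1
  }
  K <- function(z) exp(-z^2 / 2) / sqrt(2 * pi)
  wx <- (spec$x_max - spec$x_min) / spec$M
  wy <- (spec$y_max - spec$y_min) / spec$M
  Dp <- matrix(0, spec$M, spec$M)
  for (i in seq_len(spec$M)) {
    for (j in seq_len(spec$M)) {
      cx <- spec$x_min + (i - 0.5) * wx
      cy <- spec$y_min + (j - 0.5) * wy
      s <- 0
      for (k in seq_len(n)) {
        s <- s + K((cx - px[k]) / (h * sx)) * K((cy - py[k]) / (h * sy))
      }
      Dp[i, j] <- s / (n * h)
    }
  }
  Dp / sum(Dp)
}

# p^(n) = sum_{(i,j | D^(n) >= D^(s))} D^(s) / sum over the same blocks of D^(n)
oracle_pn <- function(Ds, Dn) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(Ds))) {
    for (j in seq_len(ncol(Ds))) {
      if (Dn[i, j] >= Ds[i, j]) {
        num <- num + Ds[i, j]
        den <- den + Dn[i, j]
      }
    }
  }
  if (den == 0) return(0)
  min(1, max(0, num / den))
}

# D^(t)_ij = (D^(s)_ij - p_n D^(n)_ij) / p_t, clipped at 0, renormalized
oracle_subtract <- function(Ds, Dn, p_n) {
  Dt <- matrix(0, nrow(Ds), ncol(Ds))
  for (i in seq_len(nrow(Ds))) {
    for (j in seq_len(ncol(Ds))) {
      v <- (Ds[i, j] - p_n * Dn[i, j]) / (1 - p_n)
      Dt[i, j] <- max(0, v)
    }
  }
  Dt / sum(Dt)
}

# c(x) = p_t f_t(x) / (p_t f_t(x) + p_n f_n(x)); empty blocks get the prior
oracle_conf <- function(Dt, Dn, p_t, p_n) {
  cm <- matrix(0, nrow(Dt), ncol(Dt))
  for (i in seq_len(nrow(Dt))) {
    for (j in seq_len(ncol(Dt))) {
      num <- p_t * Dt[i, j]
      den <- num + p_n * Dn[i, j]
      cm[i, j] <- if (den > 0) num / den else p_t
    }
  }
  cm
}

# c_i = sum_j c(x_ij) / n_i
oracle_contig_score <- function(frag_conf) sum(frag_conf) / length(frag_conf)

# AUC by exhaustive pair counting over all positive x negative pairs,
# ties counted 1/2
oracle_auc <- function(scores, is_pos) {
  pos <- scores[is_pos]; neg <- scores[!is_pos]
  s <- 0
  for (p in pos) {
    for (q in neg) {
      s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  s / (length(pos) * length(neg))
}

# Pearson r from the definitional sums
oracle_pearson <- function(a, b) {
  n <- length(a)
  ma <- sum(a) / n; mb <- sum(b) / n
  num <- sum((a - ma) * (b - mb))
  num / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# Density-grid object wrapper for hand-built mass matrices (shared unit spec)
hand_grid <- function(mass, n = 100) {
  M <- nrow(mass)
  structure(list(spec = grid_spec(0, 1, 0, 1, M = M), mass = mass,
                 n = n, h = n^(-1 / 6), sd = c(x = 1, y = 1)),
            class = "density_grid")
}

# Disjoint 4x4 target/background mass patterns used by the mixture tests
mixture_fixtures <- function() {
  T_mass <- matrix(0, 4, 4)
  T_mass[1, 1] <- 0.4; T_mass[1, 2] <- 0.25; T_mass[2, 1] <- 0.2; T_mass[2, 2] <- 0.15
  N_mass <- matrix(0, 4, 4)
  N_mass[3, 3] <- 0.5; N_mass[4, 4] <- 0.3; N_mass[3, 4] <- 0.2
  list(T = T_mass, N = N_mass)
}
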