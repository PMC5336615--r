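test_that("estimate_contamination handles identical, disjoint and mixed grids", {
  m <- mixture_fixtures()
  T_grid <- hand_grid(m$T); N_grid <- hand_grid(m$N)

  expect_equal(estimate_contamination(N_grid, N_grid), 1) # identical -> p_n = 1
  expect_equal(estimate_contamination(T_grid, N_grid), 0) # disjoint -> p_n = 0

  S_grid <- hand_grid(0.6 * m$T + 0.4 * m$N)
  expect_equal(estimate_contamination(S_grid, N_grid), 0.4, tolerance = 1e-9)
  expect_equal(estimate_contamination(S_grid, N_grid), oracle_pn(S_grid$mass, m$N),
               tolerance = 1e-12)

  other <- hand_grid(m$N)
  other$spec <- grid_spec(0, 2, 0, 1, M = 4)
  expect_error(estimate_contamination(T_grid, other), "mismatched")
})

test_that("subtract_distribution inverts exact mixtures and clips noise", {
  m <- mixture_fixtures()
  N_grid <- hand_grid(m$N)
  S_grid <- hand_grid(0.7 * m$T + 0.3 * m$N)

  expect_equal(subtract_distribution(S_grid, N_grid, 0)$mass, S_grid$mass)
  Dt <- subtract_distribution(S_grid, N_grid, 0.3)
  expect_equal(Dt$mass, m$T, tolerance = 1e-9)
  expect_false(any(Dt$clipped))

  # over-subtraction forces a negative block: clipped to 0, renormalized
  noisy_N <- matrix(c(0.5, 0.1, 0, 0.1, 0.1, 0, 0.1, 0.1, 0), 3, 3)
  noisy_S <- matrix(c(0.1, 0.2, 0.1, 0.2, 0.1, 0.1, 0.1, 0.05, 0.05), 3, 3)
  Sg <- hand_grid(noisy_S); Ng <- hand_grid(noisy_N)
  Dt2 <- subtract_distribution(Sg, Ng, 0.5)
  expect_true(Dt2$clipped[1, 1]) # 0.1 - 0.5*0.5 < 0
  expect_equal(Dt2$mass[1, 1], 0)
  expect_equal(sum(Dt2$mass), 1, tolerance = 1e-12)
  expect_true(all(Dt2$mass >= 0))
  expect_equal(Dt2$mass, oracle_subtract(noisy_S, noisy_N, 0.5), tolerance = 1e-12)

  expect_error(subtract_distribution(Sg, Ng, 1), "indistinguishable")
})

test_that("mixture reconstruction holds when clipping does not fire", {
  m <- mixture_fixtures()
  N_grid <- hand_grid(m$N)
  for (q in c(0.2, 0.5, 0.8)) {
    Sg <- hand_grid((1 - q) * m$T + q * m$N)
    Dt <- subtract_distribution(Sg, N_grid, q)
    expect_false(any(Dt$clipped))
    expect_equal((1 - q) * Dt$mass + q * N_grid$mass, Sg$mass, tolerance = 1e-9)
  }
})

test_that("confidence_map is the per-block posterior with prior fallback", {
  Dt <- hand_grid(matrix(c(0.5, 0, 0, 0, 0.5, 0, 0, 0, 0), 3, 3))
  Dn <- hand_grid(matrix(c(0, 0.5, 0, 0.5, 0, 0, 0, 0, 0), 3, 3))
  cm <- confidence_map(Dt, Dn, 0.5, 0.5)
  expect_equal(cm[1, 1], 1) # f_n = 0, f_t > 0
  expect_equal(cm[2, 1], 0) # f_t = 0, f_n > 0
  expect_equal(cm[3, 3], 0.5) # both zero -> prior p_t
  expect_equal(cm, oracle_conf(Dt$mass, Dn$mass, 0.5, 0.5), tolerance = 1e-12)

  eq <- hand_grid(matrix(1 / 9, 3, 3))
  expect_equal(confidence_map(eq, eq, 0.5, 0.5)[2, 2], 0.5) # f_t = f_n, even prior
  expect_true(all(cm >= 0 & cm <= 1))
  expect_error(confidence_map(Dt, Dn, 0.6, 0.6), "summing to 1")
})

test_that("score_contigs averages fragment confidences per contig", {
  spec <- grid_spec(0, 1, 0, 1, M = 2)
  cmap <- matrix(c(1.0, 0.5, 1.0, 0.7), 2, 2) # (1,1)=1, (2,1)=0.5, (1,2)=1, (2,2)=0.7
  model <- list(grid = spec, conf_map = cmap)
  pts <- data.frame(
    x = c(0.2, 0.2, 0.2, 0.7, 0.7),
    y = c(0.2, 0.2, 0.7, 0.2, 0.7),
    parent_id = c("a", "a", "a", "a", "b"),
    stringsAsFactors = FALSE)
  tab <- score_contigs(pts, model)
  expect_s3_class(tab, "score_table")
  expect_equal(tab$confidence[tab$contig_id == "a"], mean(c(1, 1, 1, 0.5)))
  expect_equal(tab$n_fragments, c(4L, 1L))
  expect_equal(tab$confidence[tab$contig_id == "b"], 0.7) # single fragment
  expect_equal(tab$confidence_pct, 100 * tab$confidence)

  # contigs with no valid fragments appear with NA
  tab2 <- score_contigs(pts, model, all_parents = c("a", "b", "ghost"))
  expect_true(is.na(tab2$confidence[tab2$contig_id == "ghost"]))
  expect_equal(tab2$n_fragments[tab2$contig_id == "ghost"], 0L)

  # out-of-bounds fragments go to the nearest boundary block, with a message
  out_pts <- data.frame(x = -5, y = 0.2, parent_id = "z", stringsAsFactors = FALSE)
  expect_message(tab3 <- score_contigs(out_pts, model), "outside")
  expect_equal(tab3$confidence, 1) # clamped to block (1,1)
})

test_that("filter_by_confidence partitions strictly above the threshold", {
  contigs <- c(a = strrep("A", 600), b = strrep("C", 600), c = strrep("G", 600))
  tab <- data.frame(contig_id = c("a", "b", "c"), n_fragments = 1L,
                    confidence = c(0.9, 0.7, 0.2), stringsAsFactors = FALSE)
  parts <- filter_by_confidence(tab, contigs, threshold = 0.7)
  expect_identical(names(parts$kept), "a") # 0.7 is NOT kept: strictly greater
  expect_identical(names(parts$discarded), c("b", "c"))
  expect_identical(sort(c(names(parts$kept), names(parts$discarded))),
                   sort(names(contigs)))

  expect_length(filter_by_confidence(tab, contigs, 0)$kept, 3)
  expect_length(filter_by_confidence(tab, contigs, 1)$kept, 0)
})

test_that("exact mixture recovery across the q grid", {
  m <- mixture_fixtures()
  N_grid <- hand_grid(m$N)
  for (q in seq(0, 0.9, by = 0.1)) {
    S_grid <- hand_grid((1 - q) * m$T + q * m$N)
    p_hat <- estimate_contamination(S_grid, N_grid)
    expect_equal(p_hat, q, tolerance = 1e-9)
    expect_equal(subtract_distribution(S_grid, N_grid, p_hat)$mass, m$T,
                 tolerance = 1e-9)
  }
})

test_that("an uncontaminated sample scored against a disjoint control is confident", {
  smp <- sample_fragments(fx$target, 60, seed = 61, prefix = "t")$contigs
  ctl <- sample_fragments(fx$contam1, 60, seed = 62, prefix = "n")$contigs
  fit <- decontaminate(smp, ctl, M = 40)
  expect_lt(fit$p_n, 0.1)
  expect_true(all(fit$scores$confidence >= 0.99))
  expect_equal(nrow(fit$scores), length(smp))
})

test_that("identical sample and control abort with the pure-contamination signal", {
  ctl <- sample_fragments(fx$contam1, 40, seed = 63, prefix = "n")$contigs
  err <- tryCatch(decontaminate(ctl, ctl, M = 30), condition = identity)
  expect_s3_class(err, "sagclean_pure_contamination")
  expect_equal(err$p_n, 1)
  expect_match(conditionMessage(err), "indistinguishable")
})

test_that("end-to-end contamination estimates track the truth and stay monotone", {
  rates <- c(0, 0.25, 0.5, 0.75)
  p_hat <- vapply(seq_along(rates), function(i) {
    b <- make_benchmark(rate = rates[i], total = 120, seed = 7000 + 10 * i)
    decontaminate(b$dataset$contigs, b$control, M = 40)$p_n
  }, numeric(1))
  expect_true(all(diff(p_hat) > 0))
  expect_true(all(abs(p_hat - rates) <= 0.1))
})
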