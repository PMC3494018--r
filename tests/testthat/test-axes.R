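test_that("axis PC1 matches a power-iteration oracle on an exact fixture", {
  r <- matrix(0.5, 3, 3); diag(r) <- 1
  x <- exact_correlation_data(40, r, seed = 8)
  colnames(x) <- c("a", "b", "c")
  rownames(x) <- paste0("s", 1:40)
  m <- std_matrix(x)
  panel <- axis_panel(1, "exp1", list(c("a", "b", "c")))
  e <- fit_axis_pc1(m, panel, 1)
  # leading eigenvalue of the equicorrelated matrix is 1 + 2*0.5 = 2
  expect_equal(e$pve_pc1, 2 / 3 * 100, tolerance = 1e-8)
  oracle <- power_iteration_pc1(manual_correlation(x))
  expect_equal(e$pve_pc1, oracle$value / 3 * 100, tolerance = 1e-8)
  v_o <- oracle$vector / sqrt(sum(oracle$vector^2))
  if (sum(v_o) < 0) v_o <- -v_o
  expect_equal(unname(e$loadings), v_o, tolerance = 1e-8)
  expect_equal(unname(e$scores), as.numeric(x %*% v_o), tolerance = 1e-8)
})

test_that("PC1 equals the dense eigendecomposition oracle on random panels", {
  set.seed(21)
  for (p in c(4, 8, 12)) {
    n <- 60
    base <- matrix(rnorm(n), n, 1)
    x <- base %*% matrix(runif(p, 0.5, 1), 1) + matrix(rnorm(n * p), n)
    x <- scale(x)[, ]
    colnames(x) <- paste0("g", 1:p)
    rownames(x) <- paste0("s", 1:n)
    panel <- axis_panel(1, "exp1", list(colnames(x)))
    e <- fit_axis_pc1(std_matrix(x), panel, 1)
    oracle <- power_iteration_pc1(manual_correlation(x))
    expect_equal(e$pve_pc1, oracle$value / p * 100, tolerance = 1e-8)
    v_o <- oracle$vector
    if (sum(v_o) < 0) v_o <- -v_o
    expect_equal(unname(e$loadings), v_o, tolerance = 1e-7)
  }
})

test_that("perfectly correlated pair scores as sqrt(2)-scaled common value", {
  z <- rnorm(20)
  z <- (z - mean(z)) / sd(z)
  x <- cbind(a = z, b = z)
  rownames(x) <- paste0("s", 1:20)
  e <- fit_axis_pc1(std_matrix(x), axis_panel(1, "e", list(c("a", "b"))), 1)
  expect_equal(e$pve_pc1, 100)
  expect_equal(unname(e$scores), z * sqrt(2), tolerance = 1e-10)
})

test_that("uncorrelated probes give pve near the 1/p floor", {
  set.seed(5)
  p <- 10; n <- 4000
  x <- scale(matrix(rnorm(n * p), n))[, ]
  colnames(x) <- paste0("g", 1:p)
  rownames(x) <- paste0("s", 1:n)
  e <- fit_axis_pc1(std_matrix(x), axis_panel(1, "e", list(colnames(x))), 1)
  expect_lt(abs(e$pve_pc1 - 10), 2.5)
})

test_that("orientation is deterministic under probe reordering", {
  co <- generate_cohort(small_config(seed = 17))
  m <- normalize_pipeline(co$ct, co$samples)$matrix
  e1 <- fit_axis_pc1(m, co$panel, 1)
  probes <- rev(panel_probes(co$panel, 1))
  panel_rev <- axis_panel(1, "exp1", list(probes))
  e2 <- fit_axis_pc1(m, panel_rev, 1)
  expect_equal(e2$scores, e1$scores, tolerance = 1e-10)  # no sign flip
  expect_gt(sum(e1$loadings), 0)
  expect_error(fit_axis_pc1(m, axis_panel(1, "e", list(c("zz", "ax1_p01"))),
                            1), "panel_too_small")
})

test_that("missing-probe scores use rescaled loadings and a half-panel rule", {
  set.seed(33)
  p <- 10
  l <- rep(1 / sqrt(p), p)
  names(l) <- paste0("g", 1:p)
  entry <- list(loadings = l)
  z <- 1.3
  full <- rep(z, p)
  names(full) <- names(l)
  expect_equal(score_with_missing(entry, full), z * sqrt(p))
  one_missing <- full; one_missing[4] <- NA
  # equal loadings closed form: identical to the complete score
  expect_equal(score_with_missing(entry, one_missing), z * sqrt(p),
               tolerance = 1e-12)
  six_missing <- full; six_missing[1:6] <- NA
  expect_true(is.na(score_with_missing(entry, six_missing)))
  five_missing <- full; five_missing[1:5] <- NA
  expect_false(is.na(score_with_missing(entry, five_missing)))
})

test_that("axis correspondence reports adj R2, p, and slope sign", {
  set.seed(44)
  a <- rnorm(85); names(a) <- paste0("s", 1:85)
  self <- suppressWarnings(axis_correspondence(a, a, axis_id = 6))
  expect_equal(self$adj_r_squared, 1)
  expect_equal(self$sign_of_slope, 1)
  expect_equal(self$n_shared_samples, 85)
  # independent scores: adj R2 near 0, assessed against a permutation spread
  b <- rnorm(85); names(b) <- names(a)
  indep <- axis_correspondence(a, b)
  perm_r2 <- replicate(200, {
    bp <- sample(b); names(bp) <- names(b)
    summary(lm(bp ~ a))$adj.r.squared
  })
  expect_lt(indep$adj_r_squared, quantile(perm_r2, 0.999))
  expect_error(axis_correspondence(a[1:2], a[1:2]), "3 shared")
  const <- rep(1, 85); names(const) <- names(a)
  expect_error(axis_correspondence(a, const), "zero variance")
})

test_that("cross-platform scores anticorrelate axis by axis", {
  co <- generate_cohort(small_config(seed = 55))
  mc <- normalize_pipeline(co$ct, co$samples)$matrix
  mi <- normalize_pipeline(co$intensity, co$samples,
                           adjust_rin = FALSE)$matrix
  sc <- score_all_axes(mc, co$panel)
  si <- score_all_axes(mi, co$panel)
  # exact inversion sanity: intensity = -ct gives correlation -1
  flip <- std_matrix(-unclass(mc)[, ], platform = "log2_intensity")
  sf <- score_all_axes(flip, co$panel)
  chk0 <- cross_platform_sign_check(sc$scores, sf$scores)
  expect_true(all(chk0$pass))
  expect_true(all(abs(chk0$correlation + 1) < 1e-10))
  # generator-paired platforms: negative correlation on every axis
  chk <- cross_platform_sign_check(sc$scores, si$scores)
  expect_true(all(chk$pass))
  # shuffled sample labels destroy the correspondence
  shuffled <- si$scores
  rownames(shuffled) <- sample(rownames(shuffled))
  chk2 <- cross_platform_sign_check(sc$scores, shuffled)
  expect_true(mean(abs(chk2$correlation)) < mean(abs(chk$correlation)) / 2)
})

test_that("score_all_axes returns the inter-axis correlation structure", {
  cfg <- cohort_config(seed = 66,
                       n_per_group = c(rural_melanesian = 25,
                                       rural_indian = 25,
                                       urban_melanesian = 25,
                                       urban_indian = 25))
  cfg$group_effects[] <- 0
  co <- generate_cohort(cfg)
  m <- normalize_pipeline(co$ct, co$samples)$matrix
  ax <- score_all_axes(m, co$panel)
  expect_equal(dim(ax$axis_cor), c(7, 7))
  # score correlations track this cohort's realized latent correlations
  # within 0.15 at n = 100 (PC1 estimation attenuates them slightly)
  lat_cor <- cor(co$truth$latent[rownames(ax$scores), ])
  expect_lt(abs(abs(ax$axis_cor["axis_1", "axis_6"]) -
                  abs(lat_cor[1, 6])), 0.15)
  expect_lt(abs(abs(ax$axis_cor["axis_4", "axis_5"]) -
                  abs(lat_cor[4, 5])), 0.15)
  expect_gt(abs(ax$axis_cor["axis_1", "axis_6"]), 0.25)
  expect_gt(abs(ax$axis_cor["axis_4", "axis_5"]), 0.15)
  # single-axis panel: 1x1 correlation matrix
  one <- score_all_axes(m, axis_panel(2, "exp1",
                                      list(panel_probes(co$panel, 2))))
  expect_equal(dim(one$axis_cor), c(1, 1))
  expect_equal(one$axis_cor[1, 1], 1)
  # panels sharing no probes with the matrix fail with named errors
  ghost <- axis_panel(c(1, 2), "exp1", list(c("q1", "q2"), c("q3", "q4")))
  expect_error(score_all_axes(m, ghost), "no axis could be scored")
})

test_that("axis scores recover the latent truth on generator cohorts", {
  co <- generate_cohort(cohort_config(seed = 77))
  m <- normalize_pipeline(mask_failed_ct(co$ct), co$samples)$matrix
  ax <- score_all_axes(m, co$panel)
  keep <- rownames(ax$scores)
  for (k in 1:7) {
    r <- cor(ax$scores[, paste0("axis_", k)], co$truth$latent[keep, k],
             use = "complete.obs")
    expect_gt(abs(r), 0.9)
    # Ct inverts the sign: oriented scores track -latent
    expect_lt(r, 0)
  }
})
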