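test_that("outlier flagging catches a shifted sample and respects limits", {
  set.seed(3)
  v <- matrix(rnorm(10 * 6, mean = 20, sd = 0.2), 10, 6,
              dimnames = list(paste0("s", 1:10), paste0("p", 1:6)))
  v[7, ] <- v[7, ] + 10   # one sample shifted by +10 cycles
  m <- expression_matrix(v, platform = "ct")
  expect_identical(flag_outlier_samples(m, k_mad = 3), "s7")
  expect_identical(flag_outlier_samples(m, k_mad = Inf), character(0))
  flat <- expression_matrix(matrix(20, 6, 4,
                                   dimnames = list(paste0("s", 1:6),
                                                   paste0("p", 1:4))), "ct")
  expect_warning(flagged <- flag_outlier_samples(flat), "zero spread")
  expect_identical(flagged, character(0))
  expect_error(flag_outlier_samples(expression_matrix(v[1:3, ], "ct")),
               "at least 5")
})

test_that("median centering zeroes each probe's median and drops thin probes", {
  v <- cbind(p1 = c(1, 2, 3), p2 = c(5, 5, 5), p3 = c(1, 2, 100),
             p4 = c(7, NA, NA))
  rownames(v) <- paste0("s", 1:3)
  m <- median_center(expression_matrix(v, "log2_intensity"))
  expect_equal(unclass(m)[, "p1"], c(s1 = -1, s2 = 0, s3 = 1))
  expect_equal(unclass(m)[, "p2"], c(s1 = 0, s2 = 0, s3 = 0))
  expect_equal(attr(m, "probes_dropped"), "p4")   # <2 observed values
  expect_equal(apply(unclass(m), 2, median), c(p1 = 0, p2 = 0, p3 = 0))
  # median by direct sort on an even count
  v2 <- cbind(p = c(1, 2, 4, 100))
  rownames(v2) <- paste0("s", 1:4)
  m2 <- median_center(expression_matrix(v2, "log2_intensity"))
  expect_equal(as.numeric(unclass(m2)), c(-2, -1, 1, 97))
})

test_that("rin_adjust residualizes category effects exactly", {
  s <- sample_table(paste0("s", 1:6), "rural", "indian", "male",
                    age = 30, bmi = 22,
                    rin = c(4, 4, 7, 7, 9, 9))   # POOR/OK/GOOD pairs
  # probe perfectly explained by category -> residuals all zero
  v <- cbind(p1 = c(-1, -1, 0, 0, 1, 1), p2 = c(0.5, -0.5, 1, -1, 2, -2))
  rownames(v) <- s$sample_id
  m <- expression_matrix(v, "ct", stage = "median_centered",
                         sample_ids = s$sample_id)
  adj <- rin_adjust(m, s)
  expect_equal(unname(unclass(adj$matrix)[, "p1"]), rep(0, 6))
  expect_equal(unname(adj$effects["p1", ]),
               c(-1, 0, 1))   # fitted POOR/OK/GOOD means
  # residuals orthogonal to category indicators (machine tolerance)
  for (lv in c("POOR", "OK", "GOOD")) {
    expect_lt(abs(mean(unclass(adj$matrix)[s$rin_category == lv, "p2"])),
              1e-12)
  }
  # BAD samples are a contract violation here
  s_bad <- s; s_bad$rin[1] <- 2; s_bad$rin_category <- categorize_rin(s_bad$rin)
  expect_error(rin_adjust(m, s_bad), "BAD")
})

test_that("rin_adjust degenerates to centering with one category and warns on singletons", {
  s1 <- sample_table(paste0("s", 1:4), "urban", "indian", "male",
                     age = 30, bmi = 22, rin = c(7, 7.5, 6.5, 7.2))
  v <- cbind(p1 = c(1, 2, 3, 4))
  rownames(v) <- s1$sample_id
  m <- expression_matrix(v, "ct", stage = "median_centered")
  expect_warning(adj <- rin_adjust(m, s1), "fewer than 2")
  expect_equal(unname(unclass(adj$matrix)[, "p1"]), c(1, 2, 3, 4) - 2.5)

  s2 <- sample_table(paste0("s", 1:5), "urban", "indian", "male",
                     age = 30, bmi = 22, rin = c(4, 7, 7.5, 6.5, 7.2))
  v2 <- cbind(p1 = c(9, 1, 2, 3, 4))
  rownames(v2) <- s2$sample_id
  m2 <- expression_matrix(v2, "ct", stage = "median_centered")
  expect_warning(adj2 <- rin_adjust(m2, s2), "single sample")
  expect_equal(unclass(adj2$matrix)[1, "p1"], 0)  # singleton residual is 0
})

test_that("rin_adjust recovers a planted category effect within 2 SE", {
  set.seed(42)
  n_per <- 30
  s <- sample_table(paste0("s", 1:(3 * n_per)), "urban", "melanesian", "male",
                    age = 30, bmi = 25,
                    rin = rep(c(4, 7, 9), each = n_per))
  sigma <- 0.5
  truth <- c(POOR = 2, OK = 0, GOOD = -2)
  y <- rep(truth, each = n_per) + rnorm(3 * n_per, sd = sigma)
  y <- y - median(y)
  m <- expression_matrix(cbind(p1 = y), "ct", stage = "median_centered",
                         sample_ids = s$sample_id)
  adj <- rin_adjust(m, s)
  se <- sigma / sqrt(n_per)
  est <- adj$effects["p1", ] - mean(adj$effects["p1", ])
  expect_true(all(abs(est - (truth - mean(truth))) < 2 * se))
})

test_that("zscore_center standardizes with n-1 sd and is idempotent", {
  v <- cbind(p1 = c(1, 2, 3), p2 = c(0, 0, 4))
  rownames(v) <- paste0("s", 1:3)
  m <- expression_matrix(v, "ct", stage = "rin_adjusted")
  z <- zscore_center(m)
  expect_equal(unname(unclass(z)[, "p1"]), c(-1, 0, 1))
  # direct-formula oracle: mean 4/3, sd over n-1
  mu <- 4 / 3; sd_ <- sqrt(sum((c(0, 0, 4) - mu)^2) / 2)
  expect_equal(unname(unclass(z)[, "p2"]), (c(0, 0, 4) - mu) / sd_)
  expect_equal(colMeans(unclass(z)), c(p1 = 0, p2 = 0))
  expect_equal(apply(unclass(z), 2, sd), c(p1 = 1, p2 = 1))
  # 4-value direct check: deviations +-2, sd = sqrt(16/3)
  z4 <- zscore_center(expression_matrix(
    cbind(p = c(0, 0, 4, 4)), "ct", stage = "rin_adjusted",
    sample_ids = paste0("s", 1:4)))
  expect_equal(as.numeric(unclass(z4)), c(-1, -1, 1, 1) * 2 / sqrt(16 / 3),
               tolerance = 1e-12)
  # idempotence on already standardized input
  z2 <- zscore_center(expression_matrix(unclass(z)[, ], "ct",
                                        stage = "rin_adjusted"))
  expect_equal(unclass(z2)[, ], unclass(z)[, ], tolerance = 1e-12)
  # zero-variance probes are dropped with a report entry
  vz <- cbind(p1 = c(1, 2, 3), pz = c(5, 5, 5))
  rownames(vz) <- paste0("s", 1:3)
  zz <- zscore_center(expression_matrix(vz, "ct", stage = "rin_adjusted"))
  expect_equal(attr(zz, "probes_dropped"), "pz")
})

test_that("pipeline output is orthogonal to RIN categories and logs attrition", {
  co <- generate_cohort(small_config(seed = 7))
  norm <- normalize_pipeline(co$ct, co$samples)
  m <- norm$matrix
  expect_identical(em_stage(m), "standardized")
  s <- co$samples[match(rownames(m), co$samples$sample_id), ]
  # zero partial correlation with category indicators, probe by probe
  for (p in colnames(m)) {
    y <- unclass(m)[, p]
    k <- !is.na(y)
    r2 <- summary(lm(y[k] ~ droplevels(s$rin_category[k])))$r.squared
    expect_lt(r2, 1e-20)
  }
  bad <- sum(co$samples$rin_category == "BAD")
  expect_equal(sum(norm$report$samples_removed$reason == "rin_bad"), bad)
  expect_equal(norm$report$stage_log,
               c("remove_bad_rin", "remove_outliers", "median_center",
                 "rin_adjust", "zscore_center"))
})

test_that("standardization is invariant to per-probe affine rescaling", {
  co <- generate_cohort(small_config(seed = 9))
  raw <- unclass(co$intensity)
  scaled <- raw
  scaled[, 1] <- 3 * scaled[, 1] + 7   # affine map of probe 1
  a <- normalize_pipeline(expression_matrix(raw, "log2_intensity"),
                          co$samples, adjust_rin = FALSE)$matrix
  b <- normalize_pipeline(expression_matrix(scaled, "log2_intensity"),
                          co$samples, adjust_rin = FALSE)$matrix
  expect_equal(unclass(a)[, ], unclass(b)[, ], tolerance = 1e-10)
})

test_that("pipeline result is invariant to sample order", {
  co <- generate_cohort(small_config(seed = 13))
  m1 <- normalize_pipeline(co$ct, co$samples)$matrix
  perm <- sample(nrow(co$ct))
  m_perm <- expression_matrix(unclass(co$ct)[perm, ], "ct")
  m2 <- normalize_pipeline(m_perm, co$samples)$matrix
  expect_equal(unclass(m2)[rownames(m1), ], unclass(m1)[, ],
               tolerance = 1e-12)
})

test_that("quality adjustment removes the degradation confound that inflates contrasts", {
  # strong degradation tied to RNA quality, no true group effects
  cfg <- cohort_config(seed = 31)
  cfg$group_effects[] <- 0
  cfg$bmi_model$coupling <- 0
  cfg$rin_model$degradation_per_unit <- 1.0
  co <- generate_cohort(cfg)
  s <- co$samples
  # adjusted pipeline: false-positive count consistent with uniform p
  adj <- normalize_pipeline(co$ct, s)$matrix
  # unadjusted: median-center + standardize only
  keep <- rownames(adj)
  raw <- expression_matrix(unclass(co$ct)[keep, ], "ct")
  unadj <- zscore_center(median_center(raw))
  count_sig <- function(m) {
    n <- 0
    for (gp in list(c("rural_melanesian", "urban_melanesian"),
                    c("rural_indian", "urban_indian"))) {
      ct <- pairwise_contrast(m, s, gp[1], gp[2])
      n <- n + sum(ct$nlp > 2, na.rm = TRUE)
    }
    n
  }
  n_adj <- count_sig(adj)
  n_unadj <- count_sig(unadj)
  expect_gt(n_unadj, 10)       # confound floods the contrasts
  expect_lte(n_adj, 6)         # adjusted data near the ~1-per-contrast law
})
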