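# shared fixture builders; everything is generated in code at test time

# a standardized ExpressionMatrix built directly from a value matrix
std_matrix <- function(values, platform = "ct") {
  expression_matrix(values, platform = platform, stage = "standardized")
}

# small cohort for fast structural tests (30 samples, 3 axes x 4 probes)
small_config <- function(seed = 101, ...) {
  cohort_config(
    n_per_group = c(rural_melanesian = 8, rural_indian = 7,
                    urban_melanesian = 8, urban_indian = 7),
    n_axes = 3, probes_per_axis = 4, extra_probes = 2,
    axis_corr = diag(3),
    group_effects = matrix(0, 4, 3, dimnames = list(
      c("rural_melanesian", "rural_indian", "urban_melanesian",
        "urban_indian"), paste0("axis_", 1:3))),
    seed = seed, ...)
}

# n x p matrix whose sample correlation matrix is EXACTLY r: orthonormalize
# iid normals, then rotate by chol(r). Columns have exact mean 0, sd 1.
exact_correlation_data <- function(n, r, seed = 1) {
  set.seed(seed)
  p <- ncol(r)
  z <- matrix(rnorm(n * p), n)
  z <- sweep(z, 2, colMeans(z))
  z <- qr.Q(qr(z))          # orthonormal, mean ~0 after centering above
  z <- sweep(z, 2, colMeans(z))
  z <- qr.Q(qr(z))
  x <- z %*% chol(r)
  sweep(x, 2, apply(x, 2, sd), "/")
}

# independent PC1 oracle: power iteration on a correlation matrix computed
# from scratch (never calls eigen/prcomp/cor)
power_iteration_pc1 <- function(r, iters = 5000, tol = 1e-14) {
  v <- rep(1 / sqrt(nrow(r)), nrow(r))
  lambda <- 0
  for (i in seq_len(iters)) {
    w <- r %*% v
    lambda_new <- sqrt(sum(w^2))
    w <- w / lambda_new
    if (max(abs(w - v)) < tol || max(abs(w + v)) < tol) {
      v <- w
      lambda <- lambda_new
      break
    }
    v <- w
    lambda <- lambda_new
  }
  list(value = lambda, vector = as.numeric(v))
}

# correlation matrix by the direct sum formula (oracle path)
manual_correlation <- function(x) {
  p <- ncol(x)
  r <- diag(p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      xi <- x[, i] - mean(x[, i])
      xj <- x[, j] - mean(x[, j])
      r[i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    }
  }
  r
}

group_levels_fixture <- function() {
  c("rural_melanesian", "rural_indian", "urban_melanesian", "urban_indian")
}

# brute-force one-way ANOVA F via sums of squares (oracle path)
manual_anova_f <- function(y, g) {
  g <- factor(g)
  gm <- mean(y)
  ssb <- 0
  ssw <- 0
  for (lv in levels(g)) {
    yg <- y[g == lv]
    ssb <- ssb + length(yg) * (mean(yg) - gm)^2
    ssw <- ssw + sum((yg - mean(yg))^2)
  }
  (ssb / (nlevels(g) - 1)) / (ssw / (length(y) - nlevels(g)))
}
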