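#' Principal components of the full expression matrix
#'
#' PCA of the standardized sample x probe matrix (probes already have unit
#' variance, so covariance PCA here is correlation-scale PCA of the raw
#' data). Returns the percent of total variance carried by every component
#' and the centered scores of the leading `k`.
#'
#' Missing cells are mean-imputed by default: on the standardized scale the
#' probe mean is zero, so absent reactions contribute nothing to any
#' component. `na_action = "drop_samples"` instead restricts to samples with
#' complete profiles.
#'
#' @param m `ExpressionMatrix` at stage `"standardized"`.
#' @param k number of leading components to return scores for (default 5).
#' @param na_action `"mean_impute"` (default) or `"drop_samples"`.
#' @return list: `eigen_share` (percent per PC, sums to 100), `pc_scores`
#'   (n x k, centered), `k`, `n_imputed_cells`, `n_samples`.
#' @export
full_pca <- function(m, k = 5, na_action = c("mean_impute", "drop_samples")) {
  assert_em(m, stage = "standardized")
  na_action <- match.arg(na_action)
  vals <- unclass(m)
  n_imputed <- 0L
  if (anyNA(vals)) {
    if (na_action == "mean_impute") {
      n_imputed <- sum(is.na(vals))
      vals[is.na(vals)] <- 0
    } else {
      vals <- vals[stats::complete.cases(vals), , drop = FALSE]
    }
  }
  if (nrow(vals) < k + 1) {
    stop("need at least k + 1 samples for ", k, " components", call. = FALSE)
  }
  pc <- stats::prcomp(vals, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  share <- 100 * ev / sum(ev)
  names(share) <- colnames(pc$x)
  avail <- sum(ev > .Machine$double.eps * ev[1] * nrow(vals))
  if (avail < k) {
    warning("matrix rank ", avail, " is below k = ", k,
            "; returning available components")
    k <- avail
  }
  list(eigen_share = share,
       pc_scores = pc$x[, seq_len(k), drop = FALSE],
       k = k, n_imputed_cells = n_imputed, n_samples = nrow(vals))
}

#' Per-PC variance explained by a cohort factor
#'
#' One-way ANOVA of each principal-component score on a metadata factor
#' (`"lifestyle"`, `"ethnicity"`, `"gender"`, `"type"`), or, with
#' `factor = "interaction"`, the lifestyle x ethnicity interaction term from
#' the two-factor model. Returns the R-squared and the regression p per PC.
#'
#' @param pc_scores n x k matrix of PC scores with sample ids as rownames.
#' @param s a `SampleTable`.
#' @param factor metadata column name, or `"interaction"`.
#' @return data.frame with `pc`, `r_squared`, `p_value`.
#' @export
factor_r2 <- function(pc_scores, s, factor) {
  s <- align_samples(s, rownames(pc_scores))
  rows <- lapply(seq_len(ncol(pc_scores)), function(j) {
    y <- pc_scores[, j]
    if (identical(factor, "interaction")) {
      fit <- stats::lm(y ~ lifestyle * ethnicity, data = s)
      tab <- stats::anova(fit)
      term <- "lifestyle:ethnicity"
      r2 <- tab[term, "Sum Sq"] / sum(tab[, "Sum Sq"])
      p <- tab[term, "Pr(>F)"]
    } else {
      g <- droplevels(factor(s[[factor]]))
      if (nlevels(g) < 2) stop("factor has a single level", call. = FALSE)
      if (any(table(g) < 2)) {
        stop("each factor level needs at least 2 samples", call. = FALSE)
      }
      fit <- stats::lm(y ~ g)
      sm <- summary(fit)
      r2 <- sm$r.squared
      p <- stats::anova(fit)["g", "Pr(>F)"]
    }
    data.frame(pc = colnames(pc_scores)[j], r_squared = r2, p_value = p)
  })
  do.call(rbind, rows)
}

#' Variance-weighted average of per-PC factor R-squared
#'
#' The headline variance-component statistic: the R-squared of a factor on
#' each of the first `k` PCs, averaged with weights proportional to each
#' PC's share of total variance (shares renormalized over the first `k`).
#' "Percent of the PC1..k variance explained by the factor."
#'
#' @param eigen_share percent-of-variance vector over all PCs (from
#'   [full_pca()]).
#' @param r2 per-PC R-squared for PCs 1..k (vector, or the data.frame from
#'   [factor_r2()]).
#' @param k number of leading PCs to average over (default 5).
#' @return list: `weighted_ve` (percent of the top-k variance block),
#'   `raw_ve` (same numerator but as percent of total matrix variance).
#' @export
weighted_variance_explained <- function(eigen_share, r2, k = 5) {
  if (is.data.frame(r2)) r2 <- r2$r_squared
  if (k > length(eigen_share) || k > length(r2)) {
    stop("k exceeds the available components", call. = FALSE)
  }
  sh <- eigen_share[seq_len(k)]
  r2 <- r2[seq_len(k)]
  list(weighted_ve = sum(sh * r2) / sum(sh) * 100,
       raw_ve = sum(sh * r2))
}

# R-squared of k score columns on a factor, by group sums (permutation path)
group_r2_matrix <- function(scores, g) {
  gi <- as.integer(g)
  counts <- tabulate(gi, nlevels(g))
  gm <- colMeans(scores)
  centered <- sweep(scores, 2, gm)
  sst <- colSums(centered^2)
  means <- rowsum(scores, gi, reorder = TRUE) / counts
  ssb <- colSums(counts * sweep(means, 2, gm)^2)
  ssb / sst
}

#' Label-permutation null for the weighted variance-explained statistic
#'
#' Permutes the metadata rows jointly against the fixed expression matrix
#' (preserving the correlation structure among factors, e.g. the
#' lifestyle x ethnicity confounding) and recomputes the weighted
#' variance-explained statistic for each factor in each permutation.
#' Per-factor independent permutation is available via
#' `mode = "per_factor"`.
#'
#' @param m `ExpressionMatrix` at stage `"standardized"`.
#' @param s `SampleTable`.
#' @param factors metadata factor columns to test (default lifestyle,
#'   ethnicity, gender).
#' @param k leading PCs in the statistic (default 5).
#' @param n_perm number of permutations, at least 100.
#' @param seed optional RNG seed for reproducibility.
#' @param mode `"joint"` (default) or `"per_factor"`.
#' @return list of class `VarCompPermutation`: `observed` (named
#'   weighted-ve), `null_quantiles` (95th/99th per factor), `empirical_p`
#'   (`(1 + #{null >= obs}) / (1 + n_perm)`), `null` (n_perm x factor
#'   matrix), `n_perm`, `seed`, `k`.
#' @export
permutation_null <- function(m, s, factors = c("lifestyle", "ethnicity",
                                               "gender"),
                             k = 5, n_perm = 1000, seed = NULL,
                             mode = c("joint", "per_factor")) {
  mode <- match.arg(mode)
  if (n_perm < 100) {
    stop("n_perm must be at least 100 for stable tail quantiles",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  pca <- full_pca(m, k = k)
  s <- align_samples(s, rownames(pca$pc_scores))
  glist <- lapply(factors, function(f) droplevels(factor(s[[f]])))
  names(glist) <- factors
  sh <- pca$eigen_share[seq_len(k)]
  w <- sh / sum(sh)
  wve <- function(g) sum(w * group_r2_matrix(pca$pc_scores, g)) * 100
  observed <- vapply(glist, wve, 0)
  n <- nrow(pca$pc_scores)
  null <- matrix(NA_real_, n_perm, length(factors),
                 dimnames = list(NULL, factors))
  for (b in seq_len(n_perm)) {
    if (mode == "joint") {
      idx <- sample.int(n)
      null[b, ] <- vapply(glist, function(g) wve(g[idx]), 0)
    } else {
      null[b, ] <- vapply(glist, function(g) wve(sample(g)), 0)
    }
  }
  structure(list(
    observed = observed,
    null_quantiles = apply(null, 2, stats::quantile, c(0.95, 0.99)),
    empirical_p = vapply(factors, function(f) {
      (1 + sum(null[, f] >= observed[f])) / (1 + n_perm)
    }, 0),
    null = null, n_perm = n_perm, seed = seed, k = k),
    class = "VarCompPermutation")
}

#' Full variance-components report
#'
#' Convenience wrapper assembling the per-PC eigenvalue shares, the per-PC
#' factor regressions (lifestyle, ethnicity, gender and the
#' lifestyle x ethnicity interaction), the weighted variance-explained
#' statistic per factor, and optionally the permutation null.
#'
#' @inheritParams permutation_null
#' @param n_perm permutations for the null (0 to skip).
#' @return list of class `VarCompReport`: `eigen_share`, `k`,
#'   `pc_table` (per-PC share, R-squared and p per factor),
#'   `weighted_ve`, `raw_ve`, `permutation` (or `NULL`).
#' @export
varcomp_report <- function(m, s, k = 5,
                           factors = c("lifestyle", "ethnicity", "gender"),
                           n_perm = 1000, seed = NULL) {
  pca <- full_pca(m, k = k)
  terms <- c(factors, "interaction")
  r2 <- lapply(terms, function(f) factor_r2(pca$pc_scores, s, f))
  names(r2) <- terms
  pc_table <- data.frame(pc = r2[[1]]$pc,
                         eigen_share = pca$eigen_share[seq_len(pca$k)])
  for (f in terms) {
    pc_table[[paste0("r2_", f)]] <- r2[[f]]$r_squared
    pc_table[[paste0("p_", f)]] <- r2[[f]]$p_value
  }
  wve <- lapply(factors, function(f)
    weighted_variance_explained(pca$eigen_share, r2[[f]], k = pca$k))
  names(wve) <- factors
  perm <- if (n_perm > 0) {
    permutation_null(m, s, factors = factors, k = pca$k, n_perm = n_perm,
                     seed = seed)
  }
  structure(list(
    eigen_share = pca$eigen_share, k = pca$k, pc_table = pc_table,
    weighted_ve = vapply(wve, `[[`, 0, "weighted_ve"),
    raw_ve = vapply(wve, `[[`, 0, "raw_ve"),
    permutation = perm), class = "VarCompReport")
}

#' @export
print.VarCompReport <- function(x, ...) {
  cat(sprintf("VarCompReport: PC1-%d carry %.1f%% of total variance\n",
              x$k, sum(x$eigen_share[seq_len(x$k)])))
  print(x$pc_table, digits = 3)
  cat("weighted variance explained (% of PC block):\n")
  print(round(x$weighted_ve, 2))
  if (!is.null(x$permutation)) {
    cat("permutation empirical p:\n")
    print(signif(x$permutation$empirical_p, 3))
  }
  invisible(x)
}
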