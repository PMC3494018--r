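#' Score one blood-transcription axis as an oriented PC1
#'
#' Computes the first principal component of the correlation matrix of the
#' panel's probes (pairwise-complete estimation, with a complete-case
#' fallback if pairwise estimation is degenerate). Samples with complete
#' panel data are scored as the loading-weighted sum of their standardized
#' values; samples missing some probes are scored by [score_with_missing()].
#' The sign of the loading vector is fixed deterministically: loadings are
#' flipped so their sum is positive (ties broken by the first probe's
#' loading), so re-runs and probe reorderings cannot silently invert an axis.
#'
#' @param m `ExpressionMatrix` at stage `"standardized"`.
#' @param panel an `AxisPanel`.
#' @param axis_id which axis of `panel` to score.
#' @param experiment optional experiment filter on `panel`.
#' @return list of class `AxisScore`: `axis_id`, `experiment_id`, `probe_ids`
#'   (panel probes present in `m`), `loadings` (unit norm), `pve_pc1`
#'   (percent of panel variance explained by PC1), `scores` (named, one per
#'   sample, `NA` when more than half the panel is missing), `n_imputed`,
#'   `cor_method`.
#' @export
fit_axis_pc1 <- function(m, panel, axis_id, experiment = NULL) {
  assert_em(m, stage = "standardized")
  probes <- panel_probes(panel, axis_id, experiment)
  experiment_id <- unique(panel$experiment_id[panel$axis_id == axis_id])
  if (!is.null(experiment)) experiment_id <- experiment
  present <- intersect(probes, colnames(m))
  if (length(present) < 2) {
    stop("panel_too_small: axis ", axis_id, " has ", length(present),
         " probes in the matrix", call. = FALSE)
  }
  x <- unclass(m)[, present, drop = FALSE]
  complete <- stats::complete.cases(x)
  if (sum(complete) < 3) {
    stop("need at least 3 samples with complete panel data for axis ",
         axis_id, call. = FALSE)
  }
  cor_method <- "pairwise"
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  eig <- if (!anyNA(r)) eigen(r, symmetric = TRUE) else NULL
  if (is.null(eig) || min(eig$values) < -1e-8) {
    warning("pairwise correlation matrix degenerate for axis ", axis_id,
            "; falling back to complete-case correlations")
    cor_method <- "complete"
    r <- stats::cor(x[complete, , drop = FALSE])
    eig <- eigen(r, symmetric = TRUE)
  }
  v <- eig$vectors[, 1]
  v <- v / sqrt(sum(v^2))
  s <- sum(v)
  if (s < 0 || (s == 0 && v[which(v != 0)[1]] < 0)) v <- -v
  names(v) <- present

  entry <- list(axis_id = axis_id, experiment_id = experiment_id[1],
                probe_ids = present, loadings = v,
                pve_pc1 = eig$values[1] / length(present) * 100,
                cor_method = cor_method)
  scores <- rep(NA_real_, nrow(x))
  names(scores) <- rownames(x)
  scores[complete] <- x[complete, , drop = FALSE] %*% v
  n_imputed <- 0L
  for (i in which(!complete)) {
    scores[i] <- score_with_missing(entry, x[i, ])
    if (!is.na(scores[i])) n_imputed <- n_imputed + 1L
  }
  entry$scores <- scores
  entry$n_imputed <- n_imputed
  class(entry) <- "AxisScore"
  entry
}

#' Score a sample with missing panel probes
#'
#' A sample missing up to half of an axis panel is still scored: the
#' loading-weighted sum over its available probes is rescaled by the ratio of
#' the total squared loading mass to the available squared loading mass, so
#' the expected score matches the complete-panel score. More than half the
#' panel missing returns `NA`.
#'
#' @param entry an `AxisScore` (or any list with a `loadings` element).
#' @param sample_values named numeric vector of the sample's standardized
#'   values for the panel probes (`NA` where missing).
#' @return scalar score, or `NA` when too few probes are available.
#' @export
score_with_missing <- function(entry, sample_values) {
  l <- entry$loadings
  x <- sample_values[names(l)]
  avail <- !is.na(x)
  if (sum(!avail) > length(l) / 2) return(NA_real_)
  sum(l[avail] * x[avail]) * sum(l^2) / sum(l[avail]^2)
}

#' Cross-experiment correspondence of axis scores
#'
#' Simple linear regression of one experiment's axis scores on the other's
#' over their shared samples, summarizing how well an axis replicates across
#' independent probe sets (adjusted R-squared, two-sided p of the slope, and
#' the slope sign).
#'
#' @param scores_a,scores_b named numeric score vectors (names = sample ids).
#' @param axis_id optional axis label carried into the result.
#' @return one-row data.frame: `axis_id`, `n_shared_samples`,
#'   `adj_r_squared`, `p_value`, `sign_of_slope`.
#' @export
axis_correspondence <- function(scores_a, scores_b, axis_id = NA_integer_) {
  shared <- intersect(names(scores_a), names(scores_b))
  a <- scores_a[shared]
  b <- scores_b[shared]
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]
  b <- b[keep]
  if (length(a) < 3) stop("need at least 3 shared samples", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance in axis scores", call. = FALSE)
  }
  fit <- stats::lm(b ~ a)
  sm <- summary(fit)
  data.frame(axis_id = axis_id, n_shared_samples = length(a),
             adj_r_squared = sm$adj.r.squared,
             p_value = sm$coefficients["a", "Pr(>|t|)"],
             sign_of_slope = sign(stats::coef(fit)[["a"]]))
}

#' Cross-platform sign check for axis scores
#'
#' Ct values fall as expression rises, so the same axis scored from a Ct
#' matrix and from a log2-intensity matrix must correlate *negatively*
#' across shared samples. Reports the per-axis correlation and a PASS/FAIL
#' call on its sign.
#'
#' @param scores_ct,scores_intensity sample x axis score matrices (as from
#'   [score_all_axes()]), with sample ids as rownames and matching axis
#'   columns.
#' @return data.frame with `axis`, `n_shared`, `correlation`, `pass`.
#' @export
cross_platform_sign_check <- function(scores_ct, scores_intensity) {
  shared <- intersect(rownames(scores_ct), rownames(scores_intensity))
  if (length(shared) < 3) stop("need at least 3 shared samples", call. = FALSE)
  axes <- intersect(colnames(scores_ct), colnames(scores_intensity))
  out <- lapply(axes, function(ax) {
    r <- stats::cor(scores_ct[shared, ax], scores_intensity[shared, ax],
                    use = "complete.obs")
    data.frame(axis = ax, n_shared = length(shared), correlation = r,
               pass = r < 0)
  })
  do.call(rbind, out)
}

#' Score every axis of a panel set
#'
#' Runs [fit_axis_pc1()] for each axis defined in `panel` (optionally within
#' one experiment) and assembles the per-sample score matrix together with
#' the inter-axis score correlation matrix (the heat-map input for axis
#' structure).
#'
#' @inheritParams fit_axis_pc1
#' @return list of class `AxisScoreTable`: `entries` (per-axis `AxisScore`
#'   objects), `scores` (sample x axis matrix), `axis_cor` (axis x axis
#'   correlation matrix), `summary` (per-axis data.frame with `n_genes`,
#'   `pve_pc1`, `n_imputed`), `errors` (named list of axes that failed).
#' @export
score_all_axes <- function(m, panel, experiment = NULL) {
  sub <- if (is.null(experiment)) panel else
    panel[panel$experiment_id == experiment, , drop = FALSE]
  axes <- sort(unique(sub$axis_id))
  entries <- list()
  errors <- list()
  for (ax in axes) {
    e <- tryCatch(fit_axis_pc1(m, panel, ax, experiment),
                  error = function(err) err)
    if (inherits(e, "error")) errors[[as.character(ax)]] <- conditionMessage(e)
    else entries[[as.character(ax)]] <- e
  }
  if (!length(entries)) {
    stop("no axis could be scored: ",
         paste(names(errors), unlist(errors), sep = ": ", collapse = "; "),
         call. = FALSE)
  }
  scores <- do.call(cbind, lapply(entries, `[[`, "scores"))
  colnames(scores) <- paste0("axis_", names(entries))
  out <- list(
    entries = entries, scores = scores,
    axis_cor = stats::cor(scores, use = "pairwise.complete.obs"),
    summary = data.frame(
      axis_id = as.integer(names(entries)),
      experiment_id = vapply(entries, `[[`, "", "experiment_id"),
      n_genes = vapply(entries, function(e) length(e$probe_ids), 0L),
      pve_pc1 = vapply(entries, `[[`, 0, "pve_pc1"),
      n_imputed = vapply(entries, `[[`, 0L, "n_imputed"),
      row.names = NULL),
    errors = errors)
  class(out) <- "AxisScoreTable"
  out
}

#' @export
print.AxisScoreTable <- function(x, ...) {
  cat("AxisScoreTable:", ncol(x$scores), "axes,", nrow(x$scores), "samples\n")
  print(x$summary)
  invisible(x)
}

#' Permutation test for group divergence of an axis score
#'
#' One-way ANOVA F statistic of the axis score on a grouping factor, with
#' significance assessed by randomly permuting group labels against scores.
#' Used to ask whether an axis separates the lifestyle-by-ethnicity groups
#' beyond chance.
#'
#' @param scores named numeric vector of axis scores.
#' @param group factor of group labels aligned with `scores`.
#' @param n_perm number of label permutations (default 199).
#' @return list with `f_observed` and `p_value`
#'   (`(1 + #{F_perm >= F_obs}) / (1 + n_perm)`).
#' @export
axis_group_permutation <- function(scores, group, n_perm = 199) {
  keep <- !is.na(scores) & !is.na(group)
  y <- scores[keep]
  g <- droplevels(factor(group[keep]))
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  f_obs <- anova_f(y, g)
  f_null <- vapply(seq_len(n_perm), function(i) anova_f(y, sample(g)), 0)
  list(f_observed = f_obs,
       p_value = (1 + sum(f_null >= f_obs)) / (1 + n_perm))
}

# one-way ANOVA F by sums of squares (fast path for permutation loops)
anova_f <- function(y, g) {
  n <- length(y)
  k <- nlevels(g)
  gm <- mean(y)
  means <- tapply(y, g, mean)
  counts <- tabulate(g, k)
  ssb <- sum(counts * (means - gm)^2)
  ssw <- sum((y - means[g])^2)
  (ssb / (k - 1)) / (ssw / (n - k))
}
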