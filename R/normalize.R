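#' Flag samples with aberrant overall Ct distributions
#'
#' Robust outlier screen on the per-sample median value: a sample is flagged
#' when its median deviates from the cohort median-of-medians by more than
#' `k_mad` robust standard deviations (MAD with the usual 1.4826 consistency
#' constant). Heavily degraded or failed arrays shift the whole Ct
#' distribution and are caught here before any modelling.
#'
#' @param m an `ExpressionMatrix` at stage `"raw"` or `"median_centered"`.
#' @param k_mad flagging threshold in robust standard deviations (default 3).
#' @return character vector of flagged sample ids (possibly empty).
#' @export
flag_outlier_samples <- function(m, k_mad = 3) {
  assert_em(m, stage = c("raw", "median_centered"))
  if (nrow(m) < 5) stop("need at least 5 samples", call. = FALSE)
  med <- apply(unclass(m), 1, stats::median, na.rm = TRUE)
  centre <- stats::median(med)
  spread <- stats::mad(med, center = centre)
  dev <- abs(med - centre)
  if (is.infinite(k_mad)) return(character(0))
  if (spread == 0) {
    warning("zero spread in per-sample medians; flagging any deviation")
    return(rownames(m)[dev > 0])
  }
  rownames(m)[dev > k_mad * spread]
}

#' Median-center each probe across samples
#'
#' Subtracts each probe's median over its non-missing samples, the first
#' normalization step for both Ct and intensity matrices. Probes with fewer
#' than two non-missing values cannot be normalized and are dropped.
#'
#' @param m an `ExpressionMatrix` at stage `"raw"`.
#' @return an `ExpressionMatrix` at stage `"median_centered"`, with attribute
#'   `probes_dropped` naming removed probes.
#' @export
median_center <- function(m) {
  assert_em(m, stage = "raw")
  vals <- unclass(m)
  n_ok <- colSums(!is.na(vals))
  drop <- n_ok < 2
  vals <- vals[, !drop, drop = FALSE]
  meds <- apply(vals, 2, stats::median, na.rm = TRUE)
  out <- em_like(sweep(vals, 2, meds), m, stage = "median_centered")
  attr(out, "probes_dropped") <- colnames(m)[drop]
  out
}

#' Regress out RNA-quality category effects
#'
#' Supervised normalization on RNA quality: for each probe, ordinary
#' least-squares of the median-centered value on the RIN category
#' (POOR/OK/GOOD indicators; BAD samples must have been removed upstream).
#' Because the design is a single categorical factor, the fit reduces to the
#' per-category mean, and the returned matrix holds the residuals: within
#' each category every probe has mean zero over its available samples, so
#' downstream contrasts cannot be driven by RNA degradation.
#'
#' @param m an `ExpressionMatrix` at stage `"median_centered"`.
#' @param s a `SampleTable` covering the samples of `m`.
#' @return list with `matrix` (residual `ExpressionMatrix`, stage
#'   `"rin_adjusted"`) and `effects` (probe x category matrix of fitted
#'   category means; `NA` where a category had no data for the probe).
#' @export
rin_adjust <- function(m, s) {
  assert_em(m, stage = "median_centered")
  s <- align_samples(s, rownames(m))
  if (any(s$rin_category == "BAD")) {
    stop("BAD RIN-category samples must be removed before adjustment",
         call. = FALSE)
  }
  cat <- droplevels(factor(s$rin_category, levels = rin_levels()))
  if (nlevels(cat) < 2) {
    warning("fewer than 2 RIN categories present; adjustment reduces to mean centering")
  }
  n_per <- table(cat)
  if (any(n_per == 1)) {
    warning("RIN category with a single sample: ",
            paste(names(n_per)[n_per == 1], collapse = ", "),
            " (its residuals are identically zero)")
  }
  vals <- unclass(m)
  effects <- matrix(NA_real_, ncol(vals), nlevels(cat),
                    dimnames = list(colnames(vals), levels(cat)))
  for (lv in levels(cat)) {
    rows <- which(cat == lv)
    mu <- colMeans(vals[rows, , drop = FALSE], na.rm = TRUE)
    mu[is.nan(mu)] <- NA_real_   # probe entirely missing in this category
    effects[, lv] <- mu
    vals[rows, ] <- sweep(vals[rows, , drop = FALSE], 2, ifelse(is.na(mu), 0, mu))
  }
  list(matrix = em_like(vals, m, stage = "rin_adjusted"), effects = effects)
}

#' Standardize probes to z-scores and re-center
#'
#' Per probe: subtract the mean, divide by the sample standard deviation
#' (n - 1 denominator), then subtract the mean once more. The second
#' centering is a no-op on complete data but not in the presence of missing
#' values, and is kept to preserve the stated order of operations.
#' Zero-variance probes cannot be standardized and are dropped.
#'
#' @param m an `ExpressionMatrix` at stage `"rin_adjusted"` (or
#'   `"median_centered"` when no quality adjustment applies).
#' @return an `ExpressionMatrix` at stage `"standardized"` with per-probe
#'   mean 0 and sd 1, plus attribute `probes_dropped`.
#' @export
zscore_center <- function(m) {
  assert_em(m, stage = c("rin_adjusted", "median_centered"))
  vals <- unclass(m)
  mu <- colMeans(vals, na.rm = TRUE)
  sd_ <- apply(vals, 2, stats::sd, na.rm = TRUE)
  drop <- !is.finite(sd_) | sd_ == 0
  z <- sweep(sweep(vals[, !drop, drop = FALSE], 2, mu[!drop]), 2,
             sd_[!drop], "/")
  z <- sweep(z, 2, colMeans(z, na.rm = TRUE))
  out <- em_like(z, m, stage = "standardized")
  attr(out, "probes_dropped") <- colnames(vals)[drop]
  out
}

#' Full supervised normalization pipeline
#'
#' Applies, in order: removal of BAD RIN-category samples, removal of samples
#' with outlying overall value distributions, per-probe median centering,
#' RIN-category regression ([rin_adjust()]), and z-score standardization with
#' re-centering ([zscore_center()]). The output matrix is orthogonal to the
#' RIN-category indicators probe by probe.
#'
#' @param m raw `ExpressionMatrix`.
#' @param s `SampleTable` covering the samples of `m`.
#' @param k_mad outlier threshold passed to [flag_outlier_samples()].
#' @param adjust_rin set `FALSE` to skip the quality regression (intensity
#'   data with uniform RNA quality).
#' @return list with `matrix` (stage `"standardized"`) and `report`, a
#'   `NormalizationReport`: `samples_removed` and `probes_removed` data
#'   frames with reasons, `per_probe_rin_coefficients`, and `stage_log`.
#' @export
normalize_pipeline <- function(m, s, k_mad = 3, adjust_rin = TRUE) {
  assert_em(m, stage = "raw")
  s <- align_samples(s, rownames(m))
  stage_log <- character(0)
  samples_removed <- data.frame(sample_id = character(0),
                                reason = character(0))
  probes_removed <- data.frame(probe_id = character(0),
                               reason = character(0))

  bad <- s$sample_id[s$rin_category == "BAD"]
  if (length(bad)) {
    samples_removed <- rbind(samples_removed,
                             data.frame(sample_id = bad, reason = "rin_bad"))
    m <- em_like(unclass(m)[!rownames(m) %in% bad, , drop = FALSE], m)
  }
  stage_log <- c(stage_log, "remove_bad_rin")

  out_ids <- flag_outlier_samples(m, k_mad = k_mad)
  if (length(out_ids)) {
    samples_removed <- rbind(
      samples_removed,
      data.frame(sample_id = out_ids, reason = "ct_distribution_outlier"))
    m <- em_like(unclass(m)[!rownames(m) %in% out_ids, , drop = FALSE], m)
  }
  stage_log <- c(stage_log, "remove_outliers")

  m <- median_center(m)
  if (length(attr(m, "probes_dropped"))) {
    probes_removed <- rbind(
      probes_removed,
      data.frame(probe_id = attr(m, "probes_dropped"),
                 reason = "insufficient_data"))
  }
  stage_log <- c(stage_log, "median_center")

  effects <- NULL
  if (adjust_rin) {
    adj <- rin_adjust(m, s)
    m <- adj$matrix
    effects <- adj$effects
    stage_log <- c(stage_log, "rin_adjust")
  }

  m <- zscore_center(m)
  if (length(attr(m, "probes_dropped"))) {
    probes_removed <- rbind(
      probes_removed,
      data.frame(probe_id = attr(m, "probes_dropped"),
                 reason = "zero_variance"))
  }
  stage_log <- c(stage_log, "zscore_center")

  report <- structure(
    list(samples_removed = samples_removed, probes_removed = probes_removed,
         per_probe_rin_coefficients = effects, stage_log = stage_log),
    class = "NormalizationReport")
  list(matrix = m, report = report)
}

#' @export
print.NormalizationReport <- function(x, ...) {
  cat("NormalizationReport\n",
      " stages: ", paste(x$stage_log, collapse = " -> "), "\n",
      " samples removed: ", nrow(x$samples_removed), "\n",
      " probes removed: ", nrow(x$probes_removed), "\n", sep = "")
  invisible(x)
}
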