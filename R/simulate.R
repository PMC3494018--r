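#' Configuration for the synthetic cohort generator
#'
#' Defines a cohort with the statistical structure the pipeline assumes:
#' correlated latent axes of blood transcription, small probe panels loading
#' on each axis, group mean shifts on a subset of axes, BMI coupled to the
#' red-cell axis, RIN-dependent Ct degradation, paired Ct/intensity
#' platforms with inverted sign, and missing reactions.
#'
#' Defaults emulate a targeted qRT-PCR study of four lifestyle x ethnicity
#' groups: 106 samples (27/26/27/26), 7 axes x 10 probes plus 26 unrelated
#' probes (96 total), axes 1 and 6 correlated at +0.5 and axes 4 and 5 at
#' +0.4, and rural Indians shifted 1.5 latent standard deviations *down*
#' (lower expression, higher Ct) on axes 2 and 6.
#'
#' @param n_per_group named counts for the four groups.
#' @param n_axes,probes_per_axis,extra_probes panel geometry.
#' @param axis_corr axis correlation matrix (unit diagonal, PSD).
#' @param group_effects group x axis matrix of latent mean shifts (sd units,
#'   expression scale; negative = lower expression).
#' @param loading_range per-probe loading interval on its axis.
#' @param noise_sd per-probe idiosyncratic noise sd (expression scale).
#' @param bmi_model list: `group_means` (kg/m^2 per group), `coupling`
#'   (kg/m^2 per latent sd of axis 2), `residual_sd`.
#' @param rin_model list: `category_probs` (group x BAD/POOR/OK/GOOD),
#'   `degradation_per_unit` (Ct added per unit of 10 minus the category
#'   midpoint), `sensitivity_range` (per-probe degradation sensitivity).
#' @param platform list: `ct_intercept`, `ct_scale` (must be negative:
#'   higher expression, earlier cycle), `ct_noise_sd`,
#'   `intensity_intercept`, `intensity_scale`, `intensity_noise_sd`.
#' @param missing_rate per-cell missingness probability (each platform
#'   masked independently).
#' @param seed optional RNG seed.
#' @return list of class `CohortConfig`.
#' @export
cohort_config <- function(n_per_group = c(rural_melanesian = 27,
                                          rural_indian = 26,
                                          urban_melanesian = 27,
                                          urban_indian = 26),
                          n_axes = 7, probes_per_axis = 10,
                          extra_probes = 26,
                          axis_corr = default_axis_corr(n_axes),
                          group_effects = default_group_effects(n_axes),
                          loading_range = c(0.7, 0.9),
                          noise_sd = 0.7,
                          bmi_model = list(
                            group_means = c(rural_melanesian = 26,
                                            rural_indian = 22,
                                            urban_melanesian = 28,
                                            urban_indian = 27),
                            coupling = 0.5, residual_sd = 3),
                          rin_model = list(
                            category_probs = default_rin_probs(),
                            degradation_per_unit = 0.15,
                            sensitivity_range = c(0.5, 1.5)),
                          platform = list(
                            ct_intercept = 18, ct_scale = -1.5,
                            ct_noise_sd = 0.3,
                            intensity_intercept = 8, intensity_scale = 1,
                            intensity_noise_sd = 0.3),
                          missing_rate = 0.02, seed = NULL) {
  stopifnot(length(n_per_group) == 4, all(n_per_group >= 1))
  names(n_per_group) <- group_levels()
  if (!isSymmetric(unname(axis_corr)) ||
      any(abs(diag(axis_corr) - 1) > 1e-12)) {
    stop("axis_corr must be symmetric with unit diagonal", call. = FALSE)
  }
  if (min(eigen(axis_corr, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8) {
    stop("axis_corr is not positive semi-definite; project it to the ",
         "nearest correlation matrix (e.g. Matrix::nearPD) first",
         call. = FALSE)
  }
  if (platform$ct_scale >= 0) {
    stop("ct_scale must be negative: Ct falls as expression rises",
         call. = FALSE)
  }
  if (any(abs(rowSums(rin_model$category_probs) - 1) > 1e-8)) {
    stop("rin_model$category_probs rows must sum to 1", call. = FALSE)
  }
  structure(list(n_per_group = n_per_group, n_axes = n_axes,
                 probes_per_axis = probes_per_axis,
                 extra_probes = extra_probes, axis_corr = axis_corr,
                 group_effects = group_effects,
                 loading_range = loading_range, noise_sd = noise_sd,
                 bmi_model = bmi_model, rin_model = rin_model,
                 platform = platform, missing_rate = missing_rate,
                 seed = seed), class = "CohortConfig")
}

#' @rdname cohort_config
#' @export
default_axis_corr <- function(n_axes = 7) {
  r <- diag(n_axes)
  if (n_axes >= 6) r[1, 6] <- r[6, 1] <- 0.5
  if (n_axes >= 5) r[4, 5] <- r[5, 4] <- 0.4
  r
}

#' @rdname cohort_config
#' @export
default_group_effects <- function(n_axes = 7) {
  eff <- matrix(0, 4, n_axes,
                dimnames = list(group_levels(), paste0("axis_", 1:n_axes)))
  # shift size calibrated so the axis-level four-group ANOVA reaches ~1e-6
  # significance at n = 106, the magnitude such cohorts exhibit
  if (n_axes >= 2) eff["rural_indian", 2] <- -1.5
  if (n_axes >= 6) eff["rural_indian", 6] <- -1.5
  eff
}

default_rin_probs <- function() {
  rural <- c(BAD = 0.06, POOR = 0.32, OK = 0.38, GOOD = 0.24)
  urban <- c(BAD = 0.02, POOR = 0.18, OK = 0.40, GOOD = 0.40)
  rbind(rural_melanesian = rural, rural_indian = rural,
        urban_melanesian = urban, urban_indian = urban)
}

# midpoint of each RIN category's interval, the scale degradation acts on
rin_category_midpoints <- function() {
  c(BAD = 2, POOR = 4.5, OK = 7, GOOD = 9)
}

#' Generate a synthetic cohort
#'
#' Draws latent axis values from the configured multivariate normal, adds
#' group mean shifts, builds probe abundances as loading x axis plus
#' idiosyncratic noise, and renders the same underlying abundances on two
#' platforms: a Ct matrix (negative scale, plus RIN-category degradation and
#' measurement noise) and a log2-intensity matrix (positive scale). BMI is
#' drawn from its group mean plus the axis-2 coupling; RIN categories are
#' sampled per group and the RIN value uniformly within the category's
#' interval. Fully reproducible for a fixed `seed`.
#'
#' Degradation acts through the quality *category* (midpoint of its RIN
#' interval) with a random per-probe sensitivity, reflecting that RIN itself
#' is a noisy readout of degradation and that degradation inflates Ct
#' unevenly across amplicons.
#'
#' @param config a [cohort_config()].
#' @return list of class `Cohort`: `ct` and `intensity`
#'   (`ExpressionMatrix`), `samples` (`SampleTable`), `panel` (`AxisPanel`),
#'   `truth` (latent axis values, loadings, degradation offsets, per-probe
#'   sensitivities), and the `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "CohortConfig"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- sum(config$n_per_group)
  groups <- factor(rep(group_levels(), config$n_per_group),
                   levels = group_levels())
  sample_ids <- sprintf("S%03d", seq_len(n))

  # latent axes: correlated normals plus group shifts (expression scale)
  ch <- chol(config$axis_corr +
               diag(1e-10, config$n_axes))  # guard exact-PSD corner
  latent <- matrix(stats::rnorm(n * config$n_axes), n) %*% ch
  latent <- latent + config$group_effects[as.integer(groups), , drop = FALSE]
  colnames(latent) <- paste0("axis_", seq_len(config$n_axes))
  rownames(latent) <- sample_ids

  axis_of <- rep(seq_len(config$n_axes), each = config$probes_per_axis)
  probe_ids <- sprintf("ax%d_p%02d", axis_of,
                       sequence(rep(config$probes_per_axis, config$n_axes)))
  loadings <- stats::runif(length(probe_ids), config$loading_range[1],
                           config$loading_range[2])
  abundance <- latent[, axis_of, drop = FALSE] %*% diag(loadings) +
    matrix(stats::rnorm(n * length(probe_ids), sd = config$noise_sd), n)
  if (config$extra_probes > 0) {
    extra_ids <- sprintf("ext_p%02d", seq_len(config$extra_probes))
    abundance <- cbind(abundance,
                       matrix(stats::rnorm(n * config$extra_probes), n))
    probe_ids <- c(probe_ids, extra_ids)
    axis_of <- c(axis_of, rep(NA_integer_, config$extra_probes))
    loadings <- c(loadings, rep(NA_real_, config$extra_probes))
  }
  colnames(abundance) <- probe_ids
  rownames(abundance) <- sample_ids

  # RNA quality: category per group, RIN within the category interval
  probs <- config$rin_model$category_probs
  rin_cat <- vapply(as.character(groups), function(g) {
    sample(rin_levels(), 1, prob = probs[g, ])
  }, "")
  bounds <- list(BAD = c(1, 3), POOR = c(3, 6), OK = c(6, 8), GOOD = c(8, 10))
  rin <- vapply(rin_cat, function(cc) {
    stats::runif(1, bounds[[cc]][1], bounds[[cc]][2])
  }, 0)
  degradation <- config$rin_model$degradation_per_unit *
    (10 - rin_category_midpoints()[rin_cat])
  sensitivity <- stats::runif(length(probe_ids),
                              config$rin_model$sensitivity_range[1],
                              config$rin_model$sensitivity_range[2])

  pf <- config$platform
  ct_vals <- pf$ct_intercept + pf$ct_scale * abundance +
    outer(degradation, sensitivity) +
    matrix(stats::rnorm(n * length(probe_ids), sd = pf$ct_noise_sd), n)
  int_vals <- pf$intensity_intercept + pf$intensity_scale * abundance +
    matrix(stats::rnorm(n * length(probe_ids), sd = pf$intensity_noise_sd), n)
  dimnames(ct_vals) <- dimnames(int_vals) <- dimnames(abundance)
  if (config$missing_rate > 0) {
    ct_vals[matrix(stats::runif(length(ct_vals)) < config$missing_rate,
                   n)] <- NA_real_
    int_vals[matrix(stats::runif(length(int_vals)) < config$missing_rate,
                    n)] <- NA_real_
  }

  bm <- config$bmi_model
  bmi <- pmax(15, bm$group_means[as.character(groups)] +
                bm$coupling * latent[, min(2, config$n_axes)] +
                stats::rnorm(n, sd = bm$residual_sd))
  villages <- list(
    rural_melanesian = c("Naga", "Koro", "Nasavu", "Nauria"),
    rural_indian = c("Vatubogi", "Luvuluvu"),
    urban_melanesian = "Suva", urban_indian = "Suva")
  location <- vapply(as.character(groups), function(g) {
    v <- villages[[g]]
    if (length(v) == 1) v else sample(v, 1)
  }, "")
  samples <- sample_table(
    sample_id = sample_ids,
    lifestyle = sub("_.*", "", as.character(groups)),
    ethnicity = sub(".*_", "", as.character(groups)),
    gender = sample(c("male", "female"), n, replace = TRUE),
    age = round(stats::runif(n, 21, 65)), bmi = bmi, rin = rin,
    location = location)

  panel <- axis_panel(seq_len(config$n_axes), "exp1",
                      split(probe_ids[!is.na(axis_of)],
                            axis_of[!is.na(axis_of)]))
  truth <- list(latent = latent, group_effects = config$group_effects,
                bmi_coupling = bm$coupling, rin = rin, rin_category = rin_cat,
                degradation = degradation,
                probes = data.frame(probe_id = probe_ids, axis_id = axis_of,
                                    loading = loadings,
                                    ct_sensitivity = sensitivity))
  structure(list(
    ct = expression_matrix(ct_vals, platform = "ct", stage = "raw"),
    intensity = expression_matrix(int_vals, platform = "log2_intensity",
                                  stage = "raw"),
    samples = samples, panel = panel, truth = truth, config = config),
    class = "Cohort")
}

#' Generate a null cohort (no group effects, no BMI coupling)
#'
#' Same generative model as [generate_cohort()] with every group mean shift
#' and the BMI-axis coupling set to zero; the reference distribution for
#' false-positive-rate and permutation-calibration checks.
#'
#' @param config a [cohort_config()].
#' @return a `Cohort`, as [generate_cohort()].
#' @export
null_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "CohortConfig"))
  config$group_effects[] <- 0
  config$bmi_model$coupling <- 0
  generate_cohort(config)
}

#' @export
print.Cohort <- function(x, ...) {
  cat(sprintf("Cohort: %d samples, %d probes (%d axes), seed %s\n",
              nrow(x$ct), ncol(x$ct), x$config$n_axes,
              ifelse(is.null(x$config$seed), "unset", x$config$seed)))
  invisible(x)
}
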