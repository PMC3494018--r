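#' Regress an axis score on a covariate, overall and within strata
#'
#' Ordinary least-squares of an axis score on a numeric covariate (BMI, age,
#' ...). The overall fit is always reported; optionally the fit is repeated
#' within each level of a grouping factor and within covariate bands (e.g.
#' BMI below vs above 25, the normal-weight / overweight boundary), which is
#' how a between-group association is distinguished from a within-group one.
#'
#' @param scores named numeric vector of axis scores (names = sample ids).
#' @param s `SampleTable`.
#' @param covariate numeric metadata column name (e.g. `"bmi"`).
#' @param group_factor optional factor column for per-group fits (e.g.
#'   `"type"`); `NULL` for overall only.
#' @param band_boundary optional covariate cut point; adds fits on the
#'   below-/at-or-above-boundary strata (default `NULL`; 25 is the
#'   conventional BMI boundary).
#' @param axis_id optional axis label carried into the result.
#' @return data.frame of class `AssociationResult`: `axis_id`, `covariate`,
#'   `stratum`, `n`, `slope`, `p_value`, `adj_r_squared`. Strata with fewer
#'   than 3 usable samples or zero covariate variance are skipped and listed
#'   in the `skipped` attribute.
#' @export
regress_axis_on_covariate <- function(scores, s, covariate,
                                      group_factor = NULL,
                                      band_boundary = NULL,
                                      axis_id = NA_integer_) {
  s <- align_samples(s, names(scores))
  x <- as.numeric(s[[covariate]])
  strata <- list(overall = rep(TRUE, length(scores)))
  if (!is.null(group_factor)) {
    for (lv in levels(droplevels(factor(s[[group_factor]])))) {
      strata[[lv]] <- s[[group_factor]] == lv
    }
  }
  if (!is.null(band_boundary)) {
    strata[[paste0(covariate, "<", band_boundary)]] <- x < band_boundary
    strata[[paste0(covariate, ">=", band_boundary)]] <- x >= band_boundary
  }
  skipped <- character(0)
  rows <- lapply(names(strata), function(nm) {
    keep <- strata[[nm]] & !is.na(scores) & !is.na(x)
    if (sum(keep) < 3 || stats::sd(x[keep]) == 0) {
      skipped <<- c(skipped, nm)
      return(NULL)
    }
    fit <- stats::lm(scores[keep] ~ x[keep])
    sm <- summary(fit)
    data.frame(axis_id = axis_id, covariate = covariate, stratum = nm,
               n = sum(keep), slope = stats::coef(fit)[[2]],
               p_value = sm$coefficients[2, "Pr(>|t|)"],
               adj_r_squared = sm$adj.r.squared)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(axis_id = integer(0), covariate = character(0),
                      stratum = character(0), n = integer(0),
                      slope = numeric(0), p_value = numeric(0),
                      adj_r_squared = numeric(0))
  }
  attr(out, "skipped") <- skipped
  class(out) <- c("AssociationResult", "data.frame")
  out
}

#' Joint fit of a covariate and a grouping factor on an axis score
#'
#' Asks whether a covariate association survives conditioning on group
#' membership (and vice versa): fits the score on the covariate alone, on
#' the group alone, and on both jointly, reporting each term's marginal and
#' conditional p-values. When the covariate is (nearly) constant within
#' every group the conditional covariate term is not identifiable and is
#' reported as such.
#'
#' @param scores named numeric vector of axis scores.
#' @param s `SampleTable`.
#' @param covariate numeric metadata column name.
#' @param group_factor factor metadata column name (e.g. `"location"` or
#'   `"lifestyle"`).
#' @param subset optional logical vector over `s` rows or character vector
#'   of sample ids restricting the fit (e.g. one ethnicity).
#' @return list of class `JointFit`: `n`, `marginal_p_covariate`,
#'   `marginal_p_group`, `conditional_p_covariate`, `conditional_p_group`
#'   (partial F tests from the joint model), `covariate_identifiable`,
#'   and the fitted `joint_model`.
#' @export
joint_fit <- function(scores, s, covariate, group_factor, subset = NULL) {
  s <- align_samples(s, names(scores))
  keep <- rep(TRUE, nrow(s))
  if (is.logical(subset)) keep <- subset
  if (is.character(subset)) keep <- s$sample_id %in% subset
  x <- as.numeric(s[[covariate]])[keep]
  g <- droplevels(factor(s[[group_factor]][keep]))
  y <- scores[keep]
  ok <- !is.na(y) & !is.na(x) & !is.na(g)
  x <- x[ok]; g <- g[ok]; y <- y[ok]
  if (nlevels(g) < 2) {
    stop("subset must contain at least 2 levels of ", group_factor,
         call. = FALSE)
  }
  if (stats::sd(x) == 0) stop("covariate has zero variance", call. = FALSE)
  p_of <- function(fit, term) stats::anova(fit)[term, "Pr(>F)"]
  m_cov <- stats::lm(y ~ x)
  m_grp <- stats::lm(y ~ g)
  m_joint <- stats::lm(y ~ x + g)
  identifiable <- !anyNA(stats::coef(m_joint))
  d1 <- stats::drop1(m_joint, test = "F")
  structure(list(
    n = length(y),
    marginal_p_covariate = p_of(m_cov, "x"),
    marginal_p_group = p_of(m_grp, "g"),
    conditional_p_covariate = if (identifiable) d1["x", "Pr(>F)"] else
      NA_real_,
    conditional_p_group = d1["g", "Pr(>F)"],
    covariate_identifiable = identifiable,
    joint_model = m_joint), class = "JointFit")
}

#' @export
print.JointFit <- function(x, ...) {
  cat(sprintf(
    "JointFit (n=%d)\n covariate: marginal p=%.3g, conditional p=%s%s\n group: marginal p=%.3g, conditional p=%.3g\n",
    x$n, x$marginal_p_covariate,
    if (x$covariate_identifiable) sprintf("%.3g", x$conditional_p_covariate)
    else "not identifiable",
    "", x$marginal_p_group, x$conditional_p_group))
  invisible(x)
}
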