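#' Probe-level one-way ANOVA across cohort groups
#'
#' Classical one-way ANOVA of each probe's standardized values on a grouping
#' factor (default the four-level lifestyle x ethnicity `type`). Missing
#' values are dropped per probe; a probe whose missingness collapses the
#' factor below two usable groups is skipped and reported.
#'
#' @param m `ExpressionMatrix` at stage `"standardized"`.
#' @param s `SampleTable`.
#' @param factor metadata column to test (default `"type"`).
#' @return data.frame with `probe_id`, `f`, `p_value`, `df1`, `df2`, `n`;
#'   attribute `skipped` lists probes that could not be tested.
#' @export
probe_anova <- function(m, s, factor = "type") {
  assert_em(m, stage = "standardized")
  s <- align_samples(s, rownames(m))
  g0 <- factor(s[[factor]])
  if (nlevels(droplevels(g0)) < 2) stop("need at least 2 groups", call. = FALSE)
  vals <- unclass(m)
  skipped <- character(0)
  rows <- lapply(colnames(vals), function(p) {
    y <- vals[, p]
    keep <- !is.na(y)
    g <- droplevels(g0[keep])
    if (nlevels(g) < 2 || any(table(g) < 2)) {
      skipped <<- c(skipped, p)
      return(NULL)
    }
    fit <- stats::lm(y[keep] ~ g)
    tab <- stats::anova(fit)
    data.frame(probe_id = p, f = tab["g", "F value"],
               p_value = tab["g", "Pr(>F)"], df1 = tab["g", "Df"],
               df2 = tab["Residuals", "Df"], n = sum(keep))
  })
  out <- do.call(rbind, rows)
  attr(out, "skipped") <- skipped
  out
}

#' Pairwise group contrast per probe
#'
#' Two-sample t-test (equal variance by default, so that the two-group case
#' agrees exactly with one-way ANOVA, F = t^2) for every probe between two
#' groups, with the mean difference reported in standardized units. On the
#' Ct platform a *positive* mean difference means higher Ct and hence
#' *lower* expression in `group_a`; direction calls already account for
#' this inversion.
#'
#' @param m `ExpressionMatrix` at stage `"standardized"`.
#' @param s `SampleTable`.
#' @param group_a,group_b levels of `factor` to contrast.
#' @param factor metadata grouping column (default `"type"`).
#' @param nlp_threshold significance cut-off on -log10(p) for direction
#'   calls (default 2).
#' @param var_equal pooled-variance t (default); `FALSE` for Welch.
#' @return data.frame of class `ContrastResult`: `probe_id`, `group_a`,
#'   `group_b`, `mean_diff` (a minus b), `p_value`, `nlp`, `direction_call`
#'   (`up_in_a` / `down_in_a` in *expression* terms, or `ns`). The source
#'   platform is carried in the `platform` attribute.
#' @export
pairwise_contrast <- function(m, s, group_a, group_b, factor = "type",
                              nlp_threshold = 2, var_equal = TRUE) {
  assert_em(m, stage = "standardized")
  s <- align_samples(s, rownames(m))
  g <- as.character(s[[factor]])
  a_rows <- which(g == group_a)
  b_rows <- which(g == group_b)
  if (length(a_rows) < 2 || length(b_rows) < 2) {
    stop("both groups need at least 2 samples", call. = FALSE)
  }
  vals <- unclass(m)
  st <- function(rows) {
    x <- vals[rows, , drop = FALSE]
    n <- colSums(!is.na(x))
    mu <- colMeans(x, na.rm = TRUE)
    v <- colSums(sweep(x, 2, mu)^2, na.rm = TRUE) / pmax(n - 1, 1)
    list(n = n, mu = mu, v = v)
  }
  a <- st(a_rows)
  b <- st(b_rows)
  diff <- a$mu - b$mu
  if (var_equal) {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$v + (b$n - 1) * b$v) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    se <- sqrt(a$v / a$n + b$v / b$n)
    df <- se^4 / ((a$v / a$n)^2 / (a$n - 1) + (b$v / b$n)^2 / (b$n - 1))
  }
  tstat <- diff / se
  p <- 2 * stats::pt(-abs(tstat), df)
  p[a$n < 2 | b$n < 2] <- NA_real_
  nlp <- -log10(p)
  up_is_negative_diff <- em_platform(m) == "ct"
  call_ <- ifelse(is.na(nlp) | nlp <= nlp_threshold, "ns",
                  ifelse(xor(diff > 0, up_is_negative_diff),
                         "up_in_a", "down_in_a"))
  out <- data.frame(probe_id = colnames(vals), group_a = group_a,
                    group_b = group_b, mean_diff = diff, p_value = p,
                    nlp = nlp, direction_call = call_, row.names = NULL)
  attr(out, "platform") <- em_platform(m)
  class(out) <- c("ContrastResult", "data.frame")
  out
}

#' Expected false positives at an NLP threshold
#'
#' Under the global null, p-values are uniform, so the expected number of
#' probes exceeding a -log10(p) threshold is `n_probes * 10^-threshold`.
#' With ~100 probes, a threshold of 2 admits about one false positive per
#' contrast, which is why NLP > 2 serves as an approximate false discovery
#' cut-off for panels of this size.
#'
#' @param n_probes number of probes tested (>= 1).
#' @param nlp_threshold -log10(p) cut-off (> 0).
#' @return expected count of null probes past the threshold.
#' @examples
#' expected_false_positives(94, 2)
#' @export
expected_false_positives <- function(n_probes, nlp_threshold) {
  if (n_probes < 1 || nlp_threshold <= 0) {
    stop("need n_probes >= 1 and nlp_threshold > 0", call. = FALSE)
  }
  n_probes * 10^(-nlp_threshold)
}

#' Volcano table with direction-resolved gene lists
#'
#' Orders a contrast by significance and splits the significant probes into
#' up- and down-regulated lists *in expression terms*: on the Ct platform a
#' negative mean difference (earlier amplification) means higher expression.
#'
#' @param contrasts a `ContrastResult` from [pairwise_contrast()].
#' @param nlp_threshold significance cut-off on -log10(p) (default 2).
#' @return list: `table` (rows sorted by `nlp` descending, with a
#'   `significant` column), `up` and `down` (probe id vectors, expression
#'   direction in `group_a` relative to `group_b`), `expected_false_positives`.
#' @export
volcano_table <- function(contrasts, nlp_threshold = 2) {
  tab <- contrasts[order(-contrasts$nlp, contrasts$probe_id), , drop = FALSE]
  sig <- !is.na(tab$nlp) & tab$nlp > nlp_threshold
  tab$significant <- sig
  up_is_negative_diff <- identical(attr(contrasts, "platform"), "ct")
  up <- if (up_is_negative_diff) sig & tab$mean_diff < 0 else
    sig & tab$mean_diff > 0
  list(table = tab,
       up = tab$probe_id[up],
       down = tab$probe_id[sig & !up],
       expected_false_positives =
         expected_false_positives(nrow(tab), nlp_threshold))
}
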