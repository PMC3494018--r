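#' RIN quality categories
#'
#' Bins an RNA Integrity Number into the four working quality categories
#' used throughout the pipeline. Because repeat RIN measurements on the same
#' extraction can differ by a point or two, modelling the category rather
#' than the raw score avoids over-fitting RNA quality. Boundaries are
#' half-open upward, so every RIN in [0, 10] maps to exactly one category:
#' `[0, 3)` BAD, `[3, 6)` POOR, `[6, 8)` OK, `[8, 10]` GOOD.
#'
#' @param rin numeric vector of RIN scores in `[0, 10]`.
#' @return factor with levels `BAD < POOR < OK < GOOD`.
#' @examples
#' categorize_rin(c(2.9, 3, 7, 8, 10))
#' @export
categorize_rin <- function(rin) {
  if (!is.numeric(rin) || any(!is.finite(rin)) ||
      any(rin < 0) || any(rin > 10)) {
    stop("`rin` must be finite and in [0, 10]", call. = FALSE)
  }
  cut(rin, breaks = c(0, 3, 6, 8, 10),
      labels = rin_levels(), right = FALSE, include.lowest = TRUE,
      ordered_result = TRUE)
}

rin_levels <- function() c("BAD", "POOR", "OK", "GOOD")

group_levels <- function() {
  c("rural_melanesian", "rural_indian", "urban_melanesian", "urban_indian")
}

#' Per-sample metadata table
#'
#' Builds and validates the sample metadata that drives every contrast:
#' lifestyle (rural/urban), ethnicity (melanesian/indian), their four-level
#' combination `type`, gender, age, BMI, RIN (with derived `rin_category`)
#' and a free-text sampling location.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param lifestyle `"rural"` or `"urban"` per sample.
#' @param ethnicity `"melanesian"` or `"indian"` per sample.
#' @param gender `"male"` or `"female"` per sample.
#' @param age years; must be positive.
#' @param bmi kg/m^2; positive where present (`NA` allowed).
#' @param rin RNA Integrity Number in `[0, 10]`.
#' @param location optional free label (defaults to lifestyle).
#' @return data.frame of class `SampleTable` with factor columns `lifestyle`,
#'   `ethnicity`, `gender`, `type`, `rin_category`.
#' @export
sample_table <- function(sample_id, lifestyle, ethnicity, gender,
                         age, bmi, rin, location = NULL) {
  sample_id <- as.character(sample_id)
  n <- length(sample_id)
  if (anyDuplicated(sample_id)) stop("duplicate sample ids", call. = FALSE)
  lifestyle <- match_enum(lifestyle, c("rural", "urban"), n)
  ethnicity <- match_enum(ethnicity, c("melanesian", "indian"), n)
  gender <- match_enum(gender, c("male", "female"), n)
  if (any(age <= 0, na.rm = TRUE)) stop("age must be positive", call. = FALSE)
  if (any(bmi <= 0, na.rm = TRUE)) stop("bmi must be positive", call. = FALSE)
  type <- factor(paste(as.character(lifestyle), as.character(ethnicity),
                       sep = "_"), levels = group_levels())
  out <- data.frame(
    sample_id = sample_id, lifestyle = lifestyle, ethnicity = ethnicity,
    gender = gender, type = type, age = as.numeric(age), bmi = as.numeric(bmi),
    rin = as.numeric(rin), rin_category = categorize_rin(rin),
    location = if (is.null(location)) as.character(lifestyle)
               else as.character(location),
    stringsAsFactors = FALSE
  )
  class(out) <- c("SampleTable", "data.frame")
  out
}

match_enum <- function(x, levels, n) {
  x <- as.character(x)
  if (length(x) == 1) x <- rep(x, n)
  if (!all(x %in% levels)) {
    stop("values must be one of: ", paste(levels, collapse = ", "),
         call. = FALSE)
  }
  factor(x, levels = levels)
}

# align metadata rows to a matrix's samples, erroring on absent ids
align_samples <- function(s, sample_ids) {
  idx <- match(sample_ids, s$sample_id)
  if (anyNA(idx)) {
    stop("samples absent from metadata: ",
         paste(sample_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  s[idx, , drop = FALSE]
}
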