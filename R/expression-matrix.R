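#' Expression matrix container
#'
#' The object every pipeline stage transforms: a numeric sample x probe
#' matrix with a platform tag and a processing-stage tag. Platform `"ct"`
#' holds qRT-PCR cycle-threshold values, which are *inversely* proportional
#' to transcript abundance (a strongly expressed transcript crosses the
#' detection threshold at an earlier cycle); platform `"log2_intensity"`
#' holds log2 microarray intensities, directly proportional to abundance.
#' Missing measurements are `NA`.
#'
#' @param values numeric matrix, samples in rows, probes in columns. Row and
#'   column names are used as sample/probe ids when `sample_ids`/`probe_ids`
#'   are not given.
#' @param platform `"ct"` or `"log2_intensity"`.
#' @param stage processing stage, one of `"raw"`, `"median_centered"`,
#'   `"rin_adjusted"`, `"standardized"`.
#' @param sample_ids,probe_ids optional character vectors overriding dimnames.
#'
#' @return An object of class `ExpressionMatrix`: the values matrix with
#'   `platform` and `stage` attributes.
#' @examples
#' m <- expression_matrix(matrix(rnorm(6, 20), 3, 2,
#'   dimnames = list(paste0("s", 1:3), c("GATA1", "MX1"))), platform = "ct")
#' em_platform(m)
#' @export
expression_matrix <- function(values,
                              platform = c("ct", "log2_intensity"),
                              stage = c("raw", "median_centered",
                                        "rin_adjusted", "standardized"),
                              sample_ids = NULL, probe_ids = NULL) {
  platform <- match.arg(platform)
  stage <- match.arg(stage)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (samples x probes)", call. = FALSE)
  }
  if (!is.null(sample_ids)) rownames(values) <- sample_ids
  if (!is.null(probe_ids)) colnames(values) <- probe_ids
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("sample_", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("probe_", seq_len(ncol(values)))
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate probe ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  }
  if (platform == "ct" && stage == "raw") {
    bad <- values[is.finite(values)]
    if (length(bad) && (any(bad <= 0) || any(bad > 40))) {
      stop("raw Ct values must lie in (0, 40]; mask no-call sentinels first",
           call. = FALSE)
    }
  }
  structure(values, platform = platform, stage = stage,
            class = c("ExpressionMatrix", "matrix", "array"))
}

#' @rdname expression_matrix
#' @param x an `ExpressionMatrix`.
#' @export
em_platform <- function(x) attr(x, "platform")

#' @rdname expression_matrix
#' @export
em_stage <- function(x) attr(x, "stage")

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d samples x %d probes [%s, stage %s], %d missing\n",
              nrow(x), ncol(x), em_platform(x), em_stage(x), sum(is.na(x))))
  invisible(x)
}

# retag a matrix derived from `template` without re-running raw-range checks
em_like <- function(values, template, stage = em_stage(template)) {
  structure(values, platform = em_platform(template), stage = stage,
            class = c("ExpressionMatrix", "matrix", "array"))
}

assert_em <- function(m, platform = NULL, stage = NULL) {
  if (!inherits(m, "ExpressionMatrix")) {
    stop("expected an ExpressionMatrix", call. = FALSE)
  }
  if (!is.null(platform) && !em_platform(m) %in% platform) {
    stop(sprintf("expected platform %s, got %s",
                 paste(platform, collapse = "/"), em_platform(m)),
         call. = FALSE)
  }
  if (!is.null(stage) && !em_stage(m) %in% stage) {
    stop(sprintf("expected stage %s, got %s",
                 paste(stage, collapse = "/"), em_stage(m)), call. = FALSE)
  }
  invisible(m)
}
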