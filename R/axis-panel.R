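#' Blood informative transcript (BIT) axis panels
#'
#' An axis panel maps an axis of blood transcriptional variation (integer id,
#' conventionally 1-7) to the ordered list of probes that proxy it in a given
#' experiment. Each axis is summarized downstream as the first principal
#' component of its roughly ten tightly co-regulated transcripts.
#'
#' @param axis_id integer vector of axis ids (recycled against probes when
#'   building a single-axis panel).
#' @param experiment_id experiment label, e.g. `"exp1"`.
#' @param probe_ids character vector (single axis) or list of character
#'   vectors, one per `axis_id`.
#' @return data.frame of class `AxisPanel` with columns `axis_id`,
#'   `experiment_id`, `probe_id`, `probe_order`.
#' @examples
#' axis_panel(c(1, 2), "exp1", list(c("GATA1", "KLF1"), c("MX1", "OAS3")))
#' @export
axis_panel <- function(axis_id, experiment_id, probe_ids) {
  if (!is.list(probe_ids)) probe_ids <- list(probe_ids)
  if (length(axis_id) != length(probe_ids)) {
    stop("one probe vector per axis_id required", call. = FALSE)
  }
  if (any(lengths(probe_ids) == 0)) {
    stop("axis probe lists must be non-empty", call. = FALSE)
  }
  out <- do.call(rbind, lapply(seq_along(axis_id), function(i) {
    data.frame(axis_id = as.integer(axis_id[i]),
               experiment_id = as.character(experiment_id),
               probe_id = as.character(probe_ids[[i]]),
               probe_order = seq_along(probe_ids[[i]]),
               stringsAsFactors = FALSE)
  }))
  validate_axis_panel(out)
}

validate_axis_panel <- function(out) {
  dup <- duplicated(out[, c("experiment_id", "probe_id")])
  if (any(dup)) {
    stop("a probe may appear in at most one axis per experiment: ",
         paste(unique(out$probe_id[dup]), collapse = ", "), call. = FALSE)
  }
  class(out) <- c("AxisPanel", "data.frame")
  out
}

#' @rdname axis_panel
#' @param panel an `AxisPanel`.
#' @param experiment optional experiment filter.
#' @export
panel_probes <- function(panel, axis_id, experiment = NULL) {
  keep <- panel$axis_id == axis_id
  if (!is.null(experiment)) keep <- keep & panel$experiment_id == experiment
  p <- panel[keep, , drop = FALSE]
  p$probe_id[order(p$probe_order)]
}

#' Read and write axis panel definitions
#'
#' Panels are stored as YAML or JSON nested maps,
#' `{axis: {experiment: [probe, ...]}}`, e.g. `{"1": {"exp1": ["GATA1"]}}`.
#' Format is chosen by file extension (`.yml`/`.yaml` vs `.json`).
#'
#' @param path file to read or write.
#' @return `read_axis_panels()` returns an `AxisPanel`;
#'   `write_axis_panels()` returns `path` invisibly.
#' @export
read_axis_panels <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  rows <- list()
  for (ax in names(raw)) {
    for (ex in names(raw[[ax]])) {
      rows[[length(rows) + 1]] <- data.frame(
        axis_id = as.integer(ax), experiment_id = ex,
        probe_id = as.character(unlist(raw[[ax]][[ex]])),
        probe_order = seq_along(unlist(raw[[ax]][[ex]])),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no axes defined in ", path, call. = FALSE)
  validate_axis_panel(do.call(rbind, rows))
}

#' @rdname read_axis_panels
#' @export
write_axis_panels <- function(panel, path) {
  axes <- split(panel, panel$axis_id)
  out <- lapply(axes, function(a) {
    exps <- split(a, a$experiment_id)
    lapply(exps, function(e) e$probe_id[order(e$probe_order)])
  })
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(out, path)
  } else {
    jsonlite::write_json(out, path, auto_unbox = FALSE, pretty = TRUE)
  }
  invisible(path)
}
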