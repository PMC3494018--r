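#' Read an expression table from CSV/TSV
#'
#' Reads a wide delimited table into an [expression_matrix()] at stage
#' `"raw"`. The first column holds row ids; the header holds column ids.
#' Lines starting with `#` (provenance headers) are skipped. Empty cells and
#' cells equal to `na_sentinel` (an instrument no-call code, 999 in common Ct
#' exports) become missing. A long-format reader
#' (`sample, probe, value` columns) is available via `format = "long"`.
#'
#' @param path CSV (default) or TSV file; tab delimiting is inferred from a
#'   `.tsv`/`.txt` extension.
#' @param platform `"ct"` or `"log2_intensity"`.
#' @param orientation `"samples_in_rows"` (default) or `"probes_in_rows"`;
#'   the latter is transposed on read.
#' @param na_sentinel numeric no-call sentinel converted to missing
#'   (default 999); set `NULL` to disable.
#' @param format `"wide"` or `"long"`.
#' @return an `ExpressionMatrix`, stage `"raw"`.
#' @export
read_expression_table <- function(path, platform = c("ct", "log2_intensity"),
                                  orientation = c("samples_in_rows",
                                                  "probes_in_rows"),
                                  na_sentinel = 999,
                                  format = c("wide", "long")) {
  platform <- match.arg(platform)
  orientation <- match.arg(orientation)
  format <- match.arg(format)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  if (format == "long") {
    need <- c("sample", "probe", "value")
    if (!all(need %in% names(df))) {
      stop("long format requires columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    if (anyDuplicated(df[, c("sample", "probe")])) {
      stop("duplicate (sample, probe) pairs in long table", call. = FALSE)
    }
    vals <- tapply(as.numeric(df$value),
                   list(factor(df$sample, unique(df$sample)),
                        factor(df$probe, unique(df$probe))),
                   identity)
    m <- matrix(as.numeric(vals), nrow(vals), ncol(vals),
                dimnames = dimnames(vals))
  } else {
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids)) {
      stop("duplicate row ids in ", path, ": ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "),
           call. = FALSE)
    }
    if (anyDuplicated(names(df)[-1])) {
      stop("duplicate column headers in ", path, ": ",
           paste(unique(names(df)[-1][duplicated(names(df)[-1])]),
                 collapse = ", "), call. = FALSE)
    }
    body <- df[, -1, drop = FALSE]
    for (j in seq_along(body)) {
      if (!is.numeric(body[[j]])) {
        bad <- which(!is.na(body[[j]]) &
                       is.na(suppressWarnings(as.numeric(body[[j]]))))
        if (length(bad)) {
          stop(sprintf("non-numeric cell at row %d, column '%s' of %s",
                       bad[1], names(body)[j], path), call. = FALSE)
        }
        body[[j]] <- as.numeric(body[[j]])
      }
    }
    m <- as.matrix(body)
    rownames(m) <- ids
    if (orientation == "probes_in_rows") m <- t(m)
  }
  if (!is.null(na_sentinel)) m[!is.na(m) & m == na_sentinel] <- NA_real_
  expression_matrix(m, platform = platform, stage = "raw")
}

#' Write an expression matrix (or any table) as CSV
#'
#' Writers emit UTF-8, `.` decimal separator, empty cell for missing, and an
#' optional `#`-prefixed provenance header that the package readers skip.
#'
#' @param m an `ExpressionMatrix` or data.frame.
#' @param path output file.
#' @param provenance optional named character vector written as
#'   `# key=value` header lines.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(m, path, provenance = NULL) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(paste0("# ", names(provenance), "=", provenance), con)
  }
  if (inherits(m, "ExpressionMatrix") || is.matrix(m)) {
    df <- data.frame(sample_id = rownames(m), as.data.frame(unclass(m)),
                     check.names = FALSE)
  } else {
    df <- as.data.frame(m)
  }
  utils::write.table(df, con, sep = ",", na = "", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read sample metadata from CSV
#'
#' Expects columns `sample_id, lifestyle, ethnicity, gender, age, bmi, rin`
#' and optionally `location`; derived columns (`type`, `rin_category`) are
#' recomputed on read.
#'
#' @param path CSV file.
#' @return a `SampleTable`.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  sample_table(df$sample_id, df$lifestyle, df$ethnicity, df$gender,
               df$age, df$bmi, df$rin,
               location = if ("location" %in% names(df)) df$location else NULL)
}

#' Mask failed qRT-PCR reactions
#'
#' Ct values above `ct_max` are treated as failed reactions (no or late
#' amplification after pre-amplification) and set missing. Probes whose
#' missing fraction then exceeds `max_missing` are dropped, mirroring the
#' probe attrition between panel design and analysis.
#'
#' @param m an `ExpressionMatrix` with `platform = "ct"`, stage `"raw"`.
#' @param ct_max largest Ct accepted as a real measurement (default 28,
#'   suited to pre-amplified targeted panels).
#' @param max_missing probes missing in more than this fraction of samples
#'   are dropped (default 0.5).
#' @return the masked `ExpressionMatrix`, with attributes `n_masked` (cells
#'   newly set missing) and `probes_dropped` (character vector).
#' @export
mask_failed_ct <- function(m, ct_max = 28, max_missing = 0.5) {
  assert_em(m, platform = "ct", stage = "raw")
  vals <- unclass(m)
  mask <- !is.na(vals) & vals > ct_max
  vals[mask] <- NA_real_
  frac_missing <- colMeans(is.na(vals))
  drop <- frac_missing > max_missing
  out <- expression_matrix(vals[, !drop, drop = FALSE], platform = "ct",
                           stage = "raw")
  attr(out, "n_masked") <- sum(mask)
  attr(out, "probes_dropped") <- colnames(vals)[drop]
  out
}
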