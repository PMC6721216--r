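#' Timed expression matrix
#'
#' Container for a features x samples expression grid where every sample
#' carries a time stamp in hours. This is the common currency of the
#' package: raw counts, log2 CPM, probe-level log2 intensities and
#' splicing-score series are all carried as `timed_matrix` objects with a
#' `units` tag stating the scale.
#'
#' @param values numeric matrix, features in rows. Must have rownames
#'   (feature ids). Column names are sample ids; if absent, ids of the form
#'   `ZT<time>` are generated (made unique for replicate times).
#' @param sample_times numeric vector of sampling times in hours, one per
#'   column of `values`.
#' @param units one of `"counts"`, `"log2cpm"`, `"log2intensity"`,
#'   `"score"`.
#' @return an object of class `timed_matrix`: a list with elements
#'   `values`, `sample_times`, `units`.
#' @examples
#' m <- matrix(rpois(20, 50), nrow = 4,
#'             dimnames = list(paste0("g", 1:4), NULL))
#' tm <- timed_matrix(m, sample_times = seq(0, 8, by = 2), units = "counts")
#' tm
#' @export
timed_matrix <- function(values,
                         sample_times,
                         units = c("counts", "log2cpm", "log2intensity", "score")) {
  units <- match.arg(units)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (nrow(values) > 0 &&
      (is.null(rownames(values)) || anyNA(rownames(values)) ||
         any(rownames(values) == ""))) {
    stop("`values` must have complete rownames (feature ids)")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicated feature ids in `values`")
  }
  sample_times <- as.numeric(sample_times)
  if (length(sample_times) != ncol(values)) {
    stop("one sample time per column is required")
  }
  if (anyNA(sample_times)) stop("sample times must not be NA")
  if (is.null(colnames(values))) {
    colnames(values) <- make.unique(sprintf("ZT%02g", sample_times), sep = "_")
  }
  structure(
    list(values = values, sample_times = sample_times, units = units),
    class = "timed_matrix"
  )
}

#' @export
print.timed_matrix <- function(x, ...) {
  cat(sprintf(
    "timed_matrix: %d features x %d samples [%s], t = %s h\n",
    nrow(x$values), ncol(x$values), x$units,
    paste(signif(range(x$sample_times), 4), collapse = "..")
  ))
  invisible(x)
}

#' @export
dim.timed_matrix <- function(x) dim(x$values)

#' Feature ids of a timed matrix
#' @param tm a `timed_matrix`.
#' @return character vector of feature ids.
#' @export
feature_ids <- function(tm) rownames(tm$values)

#' Subset a timed matrix by feature ids
#' @param tm a `timed_matrix`.
#' @param ids feature ids to keep (order preserved as given).
#' @return a `timed_matrix` with the selected rows.
#' @export
tm_subset <- function(tm, ids) {
  missing <- setdiff(ids, feature_ids(tm))
  if (length(missing)) {
    stop("unknown feature ids: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  timed_matrix(tm$values[ids, , drop = FALSE], tm$sample_times, tm$units)
}

#' Write a timed matrix as TSV
#'
#' Plain-text dialect used throughout the package: a `# units=` comment
#' line, a `# times=` comment line with the hour stamps, then a header row
#' (`feature_id` + sample ids) and one row per feature. Row order is the
#' matrix order, so writes are deterministic.
#'
#' @param tm a `timed_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timed_matrix <- function(tm, path) {
  stopifnot(inherits(tm, "timed_matrix"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# units=%s", tm$units), con)
  writeLines(sprintf("# times=%s",
                     paste(format(tm$sample_times, trim = TRUE), collapse = ",")), con)
  df <- data.frame(feature_id = rownames(tm$values), tm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a timed matrix written by [write_timed_matrix()]
#' @param path TSV path.
#' @return a `timed_matrix`.
#' @export
read_timed_matrix <- function(path) {
  hdr <- readLines(path, n = 2L)
  if (length(hdr) < 2L || !startsWith(hdr[1], "# units=") ||
      !startsWith(hdr[2], "# times=")) {
    stop("not a timed_matrix TSV (missing # units= / # times= header)")
  }
  units <- sub("^# units=", "", hdr[1])
  times <- as.numeric(strsplit(sub("^# times=", "", hdr[2]), ",")[[1]])
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 2,
                          check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$feature_id
  timed_matrix(vals, times, units)
}
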