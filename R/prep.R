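# Count normalisation (TMM scale factors, log2 CPM) and expression /
# deduplication filters applied ahead of rhythm detection.

#' TMM normalisation factors for a count matrix
#'
#' Trimmed mean of M-values between-sample factors, computed with
#' edgeR's `calcNormFactors`: reference sample chosen by the
#' upper-quartile rule, 30%/5% trimming of M/A values, inverse
#' asymptotic-variance weights, zero features excluded pairwise, and
#' factors centred so their product is 1.
#'
#' @param counts a `timed_matrix` with units `"counts"`.
#' @return data.frame with one row per sample: `sample`, `time_h`,
#'   `lib_size`, `factor`.
#' @export
tmm_factors <- function(counts) {
  stopifnot(inherits(counts, "timed_matrix"))
  if (counts$units != "counts") stop("TMM factors require raw counts")
  lib <- colSums(counts$values)
  if (any(lib <= 0)) stop("all-zero sample: ", paste(colnames(counts$values)[lib <= 0], collapse = ", "))
  f <- edgeR::calcNormFactors(counts$values, method = "TMM")
  data.frame(sample = colnames(counts$values),
             time_h = counts$sample_times,
             lib_size = lib, factor = f,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' log2 counts-per-million
#'
#' `log2((count + prior) / (lib_size * factor + 2 * prior) * 1e6)`. The
#' pseudo-count keeps zero counts finite; its default 0.5 is configurable.
#'
#' @param counts a `timed_matrix` with units `"counts"`.
#' @param factors output of [tmm_factors()]; `NULL` means unit factors.
#' @param prior pseudo-count (> 0).
#' @return a `timed_matrix` with units `"log2cpm"`.
#' @export
log_cpm <- function(counts, factors = NULL, prior = 0.5) {
  stopifnot(inherits(counts, "timed_matrix"))
  if (counts$units != "counts") stop("log_cpm requires raw counts")
  if (prior <= 0) stop("prior must be > 0")
  lib <- colSums(counts$values)
  f <- if (is.null(factors)) rep(1, ncol(counts$values)) else factors$factor
  eff <- lib * f
  vals <- log2(sweep(counts$values + prior, 2, eff + 2 * prior, `/`) * 1e6)
  dimnames(vals) <- dimnames(counts$values)
  timed_matrix(vals, counts$sample_times, "log2cpm")
}

# plain (unlogged) CPM on effective library sizes
cpm_values <- function(counts, factors = NULL) {
  lib <- colSums(counts$values)
  f <- if (is.null(factors)) rep(1, ncol(counts$values)) else factors$factor
  sweep(counts$values, 2, lib * f, `/`) * 1e6
}

#' Filter lowly expressed features and renormalise
#'
#' Keeps features whose mean CPM over all samples is at least
#' `min_avg_cpm` (the boundary value is kept), then recomputes TMM
#' factors on the kept features only.
#'
#' @param counts a `timed_matrix` with units `"counts"`.
#' @param min_avg_cpm expression threshold, default 0.5 CPM.
#' @param factors optional precomputed [tmm_factors()] used for the CPM
#'   evaluation; recomputed from `counts` when `NULL`.
#' @return list with `kept` (feature ids), `counts` (filtered
#'   `timed_matrix`) and `factors` (recomputed on the kept features).
#' @export
filter_expressed <- function(counts, min_avg_cpm = 0.5, factors = NULL) {
  stopifnot(inherits(counts, "timed_matrix"))
  if (is.null(factors)) factors <- tmm_factors(counts)
  avg <- rowMeans(cpm_values(counts, factors))
  kept <- feature_ids(counts)[avg >= min_avg_cpm]
  if (!length(kept)) {
    warning("no features pass the expression filter")
    empty <- timed_matrix(counts$values[0, , drop = FALSE],
                          counts$sample_times, "counts")
    return(list(kept = character(0), counts = empty, factors = factors))
  }
  sub <- tm_subset(counts, kept)
  list(kept = kept, counts = sub, factors = tmm_factors(sub))
}

#' Collapse multiple transcript clusters of a gene to one row
#'
#' Array platforms can carry several transcript clusters per gene; per
#' gene and period only the cluster with the smallest rhythm p-value is
#' retained. Exact p ties are broken by larger relative amplitude, then
#' lexicographically smaller feature id.
#'
#' @param rhythm_table a rhythm results data.frame (see
#'   [detect_rhythms()]) whose `feature_id` column holds cluster ids.
#' @param cluster2gene data.frame with columns `cluster_id`, `gene_id`.
#' @return the collapsed table with an added `gene_id` column.
#' @export
collapse_transcript_clusters <- function(rhythm_table, cluster2gene) {
  m <- match(rhythm_table$feature_id, cluster2gene$cluster_id)
  if (anyNA(m)) {
    stop("clusters without gene annotation: ",
         paste(utils::head(rhythm_table$feature_id[is.na(m)], 5), collapse = ", "))
  }
  tab <- rhythm_table
  tab$gene_id <- cluster2gene$gene_id[m]
  ord <- order(tab$gene_id, tab$period_h, tab$p,
               -ifelse(is.na(tab$rel_amp), -Inf, tab$rel_amp),
               tab$feature_id)
  tab <- tab[ord, , drop = FALSE]
  keep <- !duplicated(tab[, c("gene_id", "period_h")])
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
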