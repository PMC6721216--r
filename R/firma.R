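# Probe-level splicing scores: quantile normalisation, additive
# probe/chip decomposition by median polish, residual-persistence
# scoring, and a rhythm scan of the per-gene score series.

#' Quantile-normalise a probe-level matrix
#'
#' Each column's sorted values are replaced by the cross-column mean of
#' same-rank values (ties receive the mean of their would-be quantiles),
#' making all column distributions identical. Thin wrapper over limma's
#' `normalizeQuantiles`.
#'
#' @param tm a probe-level `timed_matrix` without missing values.
#' @return a `timed_matrix` with identical column distributions.
#' @export
quantile_normalize <- function(tm) {
  stopifnot(inherits(tm, "timed_matrix"))
  if (anyNA(tm$values)) stop("missing values are not supported")
  out <- limma::normalizeQuantiles(tm$values, ties = TRUE)
  dimnames(out) <- dimnames(tm$values)
  timed_matrix(out, tm$sample_times, tm$units)
}

#' Median-polish decomposition of a probe block
#'
#' Alternating row/column median sweeps until the largest absolute change
#' in the residual grid is below `eps` (default 0.01) or `maxiter`
#' sweeps (default 10). The decomposition is
#' `block = overall + row effect (probe affinity) + column effect (chip
#' expression level) + residual`, robust to isolated outlying cells.
#'
#' @param block numeric matrix, probes x samples (>= 2 of each).
#' @param eps convergence tolerance on the residual change.
#' @param maxiter maximum number of row+column sweep rounds.
#' @return list: `overall`, `row` (probe effects), `col` (chip effects),
#'   `residuals` (same shape as `block`).
#' @export
median_polish <- function(block, eps = 0.01, maxiter = 10L) {
  if (!is.matrix(block) || nrow(block) < 2 || ncol(block) < 2) {
    stop("need a matrix with at least 2 probes and 2 samples")
  }
  r <- block
  overall <- 0
  re <- numeric(nrow(block)); ce <- numeric(ncol(block))
  for (it in seq_len(maxiter)) {
    old <- r
    rm_ <- apply(r, 1, stats::median)
    r <- r - rm_
    re <- re + rm_
    cm_ <- stats::median(ce)
    ce <- ce - cm_; overall <- overall + cm_
    cm2 <- apply(r, 2, stats::median)
    r <- sweep(r, 2, cm2)
    ce <- ce + cm2
    rm2 <- stats::median(re)
    re <- re - rm2; overall <- overall + rm2
    if (max(abs(r - old)) < eps) break
  }
  list(overall = overall, row = re, col = ce, residuals = r)
}

#' Residual-persistence splicing score per sample
#'
#' Residuals are standardised by the gene's residual MAD (scaled by
#' 1.4826); the score of sample j is the maximum over all contiguous
#' probe runs `[k..l]` of `|sum of z over the run| / sqrt(run length)`.
#' Several adjacent probes deviating in the same direction therefore
#' score higher than an isolated deviation of the same total size,
#' which is the signature of a differentially included exon region.
#'
#' @param residuals probes x samples residual matrix (from
#'   [median_polish()]).
#' @param probe_order integer ranks giving the within-gene probe order;
#'   defaults to row order.
#' @return numeric score per sample (>= 0). If the residual MAD is zero
#'   the scores are all 0 and carry attribute `zero_mad = TRUE`.
#' @export
firma_score <- function(residuals, probe_order = seq_len(nrow(residuals))) {
  if (length(probe_order) != nrow(residuals) ||
      !setequal(probe_order, seq_len(nrow(residuals)))) {
    stop("probe_order must rank every probe exactly once")
  }
  r <- residuals[order(probe_order), , drop = FALSE]
  s <- stats::mad(r)  # median absolute deviation scaled by 1.4826
  if (s < 1e-12) {
    out <- rep(0, ncol(r))
    attr(out, "zero_mad") <- TRUE
    return(out)
  }
  z <- r / s
  P <- nrow(z)
  vapply(seq_len(ncol(z)), function(j) {
    cs <- c(0, cumsum(z[, j]))
    best <- 0
    for (k in seq_len(P)) {
      for (l in k:P) {
        best <- max(best, abs(cs[l + 1] - cs[k]) / sqrt(l - k + 1))
      }
    }
    best
  }, numeric(1))
}

#' Scan probe-level data for rhythmic splicing scores
#'
#' Per gene: quantile-normalised intensities are decomposed by median
#' polish, the residual-persistence score is computed per time point,
#' and the score series is tested for rhythmicity (umbrella rank test +
#' harmonic fit) at each period. Score series with relative amplitude
#' below `rel_amp_min` are excluded before BH correction (per period);
#' genes pass at `q < q_max`. The additive chip effect absorbs
#' whole-gene expression rhythms, so only differential probe behaviour
#' can make a score series rhythmic.
#'
#' @param probe_tm probe-level `timed_matrix` (units log2intensity).
#' @param annotation data.frame `probe_id`, `gene_id`, `probe_index`.
#' @param periods periods to test, hours.
#' @param rel_amp_min relative-amplitude filter on the score series.
#' @param q_max FDR cutoff.
#' @param correction,n_perm passed to [umbrella_rank_test()].
#' @return list with `scores` (`timed_matrix` of per-gene score series)
#'   and `rhythms` (a rhythm table as in [detect_rhythms()], with
#'   `sig_pass` at `q < q_max`). Genes with fewer than 4 probes are
#'   skipped with a warning.
#' @export
rhythmic_splicing_scan <- function(probe_tm, annotation, periods = c(24, 12),
                                   rel_amp_min = 0.1, q_max = 0.1,
                                   correction = "permutation",
                                   n_perm = 20000L) {
  stopifnot(inherits(probe_tm, "timed_matrix"))
  need <- c("probe_id", "gene_id", "probe_index")
  if (!all(need %in% names(annotation))) {
    stop("annotation needs columns probe_id, gene_id, probe_index")
  }
  norm <- quantile_normalize(probe_tm)
  genes <- unique(annotation$gene_id)
  small <- character(0)
  score_rows <- list()
  for (g in genes) {
    ann <- annotation[annotation$gene_id == g, , drop = FALSE]
    if (nrow(ann) < 4) { small <- c(small, g); next }
    block <- norm$values[ann$probe_id, , drop = FALSE]
    mp <- median_polish(block)
    score_rows[[g]] <- firma_score(mp$residuals, ann$probe_index)
  }
  if (length(small)) {
    warning("skipped genes with < 4 probes: ", paste(small, collapse = ", "))
  }
  if (!length(score_rows)) stop("no gene with >= 4 probes")
  scores <- do.call(rbind, score_rows)
  rownames(scores) <- names(score_rows)
  colnames(scores) <- colnames(probe_tm$values)
  score_tm <- timed_matrix(scores, probe_tm$sample_times, "score")
  rhythms <- detect_rhythms(score_tm, periods = periods,
                            rel_amp_min = rel_amp_min, sig_mode = "q",
                            sig_threshold = q_max, robust = TRUE,
                            correction = correction, n_perm = n_perm)
  list(scores = score_tm, rhythms = rhythms)
}
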