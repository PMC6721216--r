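# Rhythm detection: harmonic (cosinor) regression with optional Huber
# IRLS, and a rank-based umbrella test for rise-then-fall patterns of
# arbitrary waveform (circular Mack-Wolfe statistics over candidate peak
# positions).

#' Harmonic (cosinor) regression of one series
#'
#' Least-squares fit of `y = m + a*cos(2*pi*t/T) + b*sin(2*pi*t/T)`.
#' With `robust = TRUE` the fit is iteratively reweighted least squares
#' with Huber weights (tuning constant 1.345, at most 50 iterations,
#' convergence 1e-8 on the coefficients), which keeps single outlying
#' time points from distorting amplitude and phase.
#'
#' @param values numeric series.
#' @param times sampling times in hours (>= 4 distinct values required).
#' @param period period T in hours (> 0).
#' @param robust use Huber IRLS instead of plain least squares.
#' @return list of class `harmonic_fit`: `mesor`, `a`, `b`, `amplitude`
#'   (`sqrt(a^2+b^2)`), `rel_amp` (amplitude / |mesor|, `NA` when the
#'   mesor is numerically zero), `peak_phase` (hours in `[0, T)`, `NA`
#'   for a flat fit), `period`, `robust`.
#' @examples
#' t <- seq(0, 22, 2)
#' harmonic_fit(5 + 2 * cos(2 * pi * t / 24), t, 24)
#' @export
harmonic_fit <- function(values, times, period, robust = TRUE) {
  if (period <= 0) stop("period must be > 0")
  if (length(values) != length(times)) stop("values/times length mismatch")
  ok <- !is.na(values)
  values <- values[ok]; times <- times[ok]
  if (length(unique(times)) < 4) stop("need at least 4 distinct time points")
  w <- 2 * pi * times / period
  X <- cbind(1, cos(w), sin(w))
  qx <- qr(X)
  rdiag <- abs(diag(qr.R(qx)))
  if (qx$rank < 3 || min(rdiag) < 1e-8 * max(rdiag)) {
    stop("degenerate design: times collapse modulo the period")
  }
  beta <- stats::lm.fit(X, values)$coefficients
  if (robust) beta <- huber_irls(X, values, beta)
  m <- beta[1]; a <- beta[2]; b <- beta[3]
  A <- sqrt(a^2 + b^2)
  phase <- if (A < 1e-12) {
    NA_real_
  } else {
    ph <- (period / (2 * pi) * atan2(b, a)) %% period
    if (ph > period - 1e-9) 0 else ph  # wrap the boundary back to 0
  }
  rel <- if (abs(m) < 1e-6) NA_real_ else A / abs(m)
  structure(list(mesor = unname(m), a = unname(a), b = unname(b),
                 amplitude = unname(A), rel_amp = unname(rel),
                 peak_phase = unname(phase), period = period,
                 robust = robust),
            class = "harmonic_fit")
}

#' @export
print.harmonic_fit <- function(x, ...) {
  cat(sprintf("harmonic_fit (T=%g h%s): mesor %.4g, amplitude %.4g, rel_amp %.4g, phase %.4g h\n",
              x$period, if (x$robust) ", robust" else "",
              x$mesor, x$amplitude,
              if (is.na(x$rel_amp)) NA else x$rel_amp,
              if (is.na(x$peak_phase)) NA else x$peak_phase))
  invisible(x)
}

# Huber IRLS; c = 1.345 gives 95% efficiency under Gaussian errors.
huber_irls <- function(X, y, beta0, k = 1.345, maxit = 50L, tol = 1e-8) {
  beta <- beta0
  for (it in seq_len(maxit)) {
    r <- y - X %*% beta
    s <- stats::median(abs(r)) / 0.6745
    if (s < 1e-12) return(beta)  # (near-)exact fit
    u <- abs(r) / s
    wts <- ifelse(u <= k, 1, k / u)
    fit <- stats::lm.wfit(X, y, as.vector(wts))
    delta <- max(abs(fit$coefficients - beta))
    beta <- fit$coefficients
    if (delta < tol) break
  }
  beta
}

## ---- umbrella rank test ----------------------------------------------

# Umbrella shapes on m circular phase bins: one shape per peak bin, with
# the trough placed antipodally (floor(m/2) bins away). Comparisons are
# directed bin pairs (a, b) meaning "bin b expected larger": all pairs
# within the rising arc trough..peak and within the falling arc
# peak..trough (the trough-peak pair counted once).
umbrella_shape_pairs <- function(m) {
  lapply(seq_len(m), function(p) {
    q <- ((p - 1 + m %/% 2) %% m) + 1
    rise <- ((q - 1 + 0:((p - q) %% m)) %% m) + 1
    fall <- ((p - 1 + 0:((q - p) %% m)) %% m) + 1
    prs <- rbind(
      do.call(rbind, lapply(seq_along(rise)[-length(rise)], function(i) {
        cbind(rise[i], rise[(i + 1):length(rise)])
      })),
      do.call(rbind, lapply(seq_along(fall)[-length(fall)], function(i) {
        cbind(fall[(i + 1):length(fall)], fall[i])
      }))
    )
    unique(prs)
  })
}

# Null mean and variance of the summed Mann-Whitney statistic for one
# shape under exchangeability of continuous values. Variance follows from
# the indicator covariances: +1/12 for comparisons sharing a source or a
# target observation, -1/12 for chained comparisons; verified against the
# Jonckheere-Terpstra closed form.
umbrella_null_moments <- function(n, M) {
  mu <- sum(n[M[, 1]] * n[M[, 2]]) / 2
  m <- length(n)
  t_out <- t_in <- numeric(m)
  for (g in seq_len(m)) {
    t_out[g] <- sum(n[M[M[, 1] == g, 2]])
    t_in[g] <- sum(n[M[M[, 2] == g, 1]])
  }
  v <- sum(n[M[, 1]] * n[M[, 2]]) / 4 +
    sum(n * (t_out^2 - t_out)) / 12 +
    sum(n * (t_in^2 - t_in)) / 12 -
    2 * sum(n * t_in * t_out) / 12
  list(mu = mu, var = v)
}

# Pairwise bin U-matrix: U[a, b] = #{x in a, y in b : y > x} + 0.5 ties.
umbrella_umat <- function(vals, bin_ind) {
  ind <- outer(vals, vals, function(a, b) (b > a) + 0.5 * (b == a))
  crossprod(bin_ind, ind %*% bin_ind)
}

# Smooth combination over shapes: log-mean-exp of the per-shape z-scores.
# Dominated by the best-matching shape but a continuous function of the
# whole z vector, which keeps the null distribution fine-grained enough
# to be calibrated by permutation.
umbrella_stat <- function(vals, grid) {
  U <- umbrella_umat(vals, grid$bin_ind)
  zs <- vapply(seq_along(grid$masks), function(i) {
    (sum(U * grid$masks[[i]]) - grid$mu[i]) / grid$sd[i]
  }, numeric(1))
  mx <- max(zs)
  list(stat = mx + log(mean(exp(zs - mx))), z = zs)
}

# Precompute everything that depends only on the folded time grid.
umbrella_grid <- function(times, period) {
  ph <- round(times %% period, 9)
  ub <- sort(unique(ph))
  bins <- match(ph, ub)
  m <- length(ub)
  if (m < 3) stop("need at least 3 distinct phase bins after folding")
  n <- tabulate(bins, m)
  shapes <- umbrella_shape_pairs(m)
  masks <- lapply(shapes, function(M) {
    mk <- matrix(0, m, m); mk[M] <- 1; mk
  })
  mom <- lapply(shapes, umbrella_null_moments, n = n)
  B <- matrix(0, length(bins), m); B[cbind(seq_along(bins), bins)] <- 1
  list(bins = bins, bin_sizes = n, m = m, shapes = shapes, masks = masks,
       mu = vapply(mom, `[[`, numeric(1), "mu"),
       sd = sqrt(vapply(mom, `[[`, numeric(1), "var")),
       bin_ind = B, phase_bins_h = ub)
}

.umbrella_cache <- new.env(parent = emptyenv())

# Permutation null of the combined statistic; depends only on the bin
# structure, so it is computed once per grid and cached. The table uses a
# private RNG stream (fixed internal seed) so results are reproducible
# and independent of the caller's RNG state.
umbrella_null_table <- function(grid, n_perm) {
  key <- paste(c(grid$bin_sizes, n_perm), collapse = ".")
  if (!is.null(.umbrella_cache[[key]])) return(.umbrella_cache[[key]])
  N <- sum(grid$bin_sizes)
  tab <- with_seed(760231L, {
    vapply(seq_len(n_perm), function(i) {
      umbrella_stat(stats::rnorm(N), grid)$stat
    }, numeric(1))
  })
  tab <- sort(tab)
  .umbrella_cache[[key]] <- tab
  tab
}

# All distinct orderings of the (possibly tied) values; used for exact
# small-sample p-values.
all_value_permutations <- function(vals) {
  n <- length(vals)
  perms <- matrix(1L, nrow = 1, ncol = 1)
  for (k in 2:n) {
    perms <- do.call(rbind, lapply(seq_len(k), function(pos) {
      left <- perms[, seq_len(pos - 1), drop = FALSE]
      right <- if (pos <= k - 1) perms[, pos:(k - 1), drop = FALSE]
      cbind(left, k, right)
    }))
  }
  perms
}

#' Rank-based umbrella test for rhythmicity
#'
#' Folds the sampling times modulo the period into ordered phase bins
#' (so a 48-h series tested at 24 h contributes two replicates per bin)
#' and scores every candidate peak position by a circular Mack-Wolfe
#' statistic: summed Mann-Whitney pair counts along the rising arc from
#' the (antipodal) trough to the peak and along the falling arc back.
#' Being rank-based, the test is invariant to monotone transforms of the
#' values and makes no waveform assumption beyond rise-then-fall.
#'
#' Combination over candidate peak shapes is controlled by `correction`:
#' \describe{
#'   \item{`"permutation"` (default)}{the per-shape z-scores are combined
#'     by log-mean-exp and referred to a permutation null of that same
#'     combined statistic (`n_perm` draws, computed once per time-grid
#'     structure and cached). This keeps the null p-value distribution
#'     uniform.}
#'   \item{`"bonferroni"`}{the smallest per-shape normal-approximation
#'     p-value times the number of shapes, capped at 1. Conservative,
#'     since neighbouring shapes are strongly correlated.}
#' }
#' For `sum(n) <= exact_limit` the p-value is computed exactly by
#' enumerating all orderings of the observed values (ties handled by
#' midrank scoring), under either correction mode.
#'
#' @param values numeric series (not all tied; all-tied input returns
#'   p = 1 with attribute `degenerate`).
#' @param times sampling times in hours.
#' @param period tested period in hours.
#' @param correction `"permutation"` or `"bonferroni"`.
#' @param n_perm size of the cached permutation null table.
#' @param exact_limit maximum total sample size for exact enumeration.
#' @return the p-value, with attribute `peak_bin_h` (phase bin of the
#'   best-matching shape, hours).
#' @export
umbrella_rank_test <- function(values, times, period,
                               correction = c("permutation", "bonferroni"),
                               n_perm = 20000L, exact_limit = 8L) {
  correction <- match.arg(correction)
  if (length(values) != length(times)) stop("values/times length mismatch")
  ok <- !is.na(values)
  values <- values[ok]; times <- times[ok]
  if (length(values) < 6) stop("need at least 6 samples")
  if (length(unique(values)) == 1L) {
    p <- 1
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  grid <- umbrella_grid(times, period)
  obs <- umbrella_stat(values, grid)
  peak_h <- grid$phase_bins_h[which.max(obs$z)]
  N <- length(values)
  if (N <= exact_limit) {
    perms <- all_value_permutations(values)
    if (correction == "permutation") {
      stats_all <- apply(perms, 1, function(ix) umbrella_stat(values[ix], grid)$stat)
      p <- mean(stats_all >= obs$stat - 1e-12)
    } else {
      z_all <- t(apply(perms, 1, function(ix) umbrella_stat(values[ix], grid)$z))
      p_shape <- vapply(seq_along(grid$masks), function(s) {
        mean(z_all[, s] >= obs$z[s] - 1e-12)
      }, numeric(1))
      p <- min(1, min(p_shape) * length(p_shape))
    }
  } else if (correction == "permutation") {
    tab <- umbrella_null_table(grid, n_perm)
    n_ge <- length(tab) - findInterval(obs$stat - 1e-12, tab)
    p <- (n_ge + 1) / (length(tab) + 1)
  } else {
    # normal approximation per shape with continuity correction and a
    # midrank tie adjustment to the variance
    tie <- tie_correction(values)
    p_shape <- stats::pnorm(
      (obs$z * grid$sd - 0.5) / (grid$sd * sqrt(tie)),
      lower.tail = FALSE
    )
    p <- min(1, min(p_shape) * length(p_shape))
  }
  attr(p, "peak_bin_h") <- peak_h
  p
}

# multiplicative variance deflation for midranks under ties
tie_correction <- function(values) {
  N <- length(values)
  tt <- table(values)
  max(1e-12, 1 - sum(tt^3 - tt) / (N^3 - N))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control: `q(i) = min_{j>=i} p(j)*n/j` on
#' the sorted p-values, mapped back to input order.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` allowed and
#'   propagated).
#' @return vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Detect rhythmic features in a timed matrix
#'
#' Per feature and period: umbrella rank test p-value plus a harmonic
#' fit (mesor, amplitude, relative amplitude, peak phase). Features with
#' relative amplitude below `rel_amp_min` are excluded *before* FDR
#' correction; BH q-values are then computed per period over the
#' remaining features. Significance is flagged either on q (dense
#' two-cycle designs) or on raw p (single-cycle designs, where FDR on p
#' is too blunt); profile defaults live in [pipeline_profile()].
#'
#' @param tm a `timed_matrix` of normalised values (log2 CPM, log2
#'   intensity or scores).
#' @param periods periods to test, hours.
#' @param rel_amp_min minimum relative amplitude (default 0.1).
#' @param sig_mode `"q"` or `"p"`: which value `sig_threshold` applies to.
#' @param sig_threshold significance cutoff.
#' @param robust robust harmonic fits.
#' @param correction passed to [umbrella_rank_test()].
#' @param n_perm passed to [umbrella_rank_test()].
#' @return data.frame with columns `feature_id`, `period_h`, `p`, `q`,
#'   `mesor`, `amplitude`, `rel_amp`, `phase_h`, `amp_pass`, `sig_pass`.
#' @export
detect_rhythms <- function(tm, periods = c(24, 12), rel_amp_min = 0.1,
                           sig_mode = c("q", "p"), sig_threshold = 0.05,
                           robust = TRUE,
                           correction = "permutation", n_perm = 20000L) {
  stopifnot(inherits(tm, "timed_matrix"))
  sig_mode <- match.arg(sig_mode)
  if (nrow(tm$values) == 0) stop("empty matrix")
  out <- list()
  for (T_h in periods) {
    ids <- feature_ids(tm)
    fits <- lapply(ids, function(id) {
      harmonic_fit(tm$values[id, ], tm$sample_times, T_h, robust = robust)
    })
    p <- vapply(ids, function(id) {
      as.numeric(umbrella_rank_test(tm$values[id, ], tm$sample_times, T_h,
                                    correction = correction, n_perm = n_perm))
    }, numeric(1))
    rel <- vapply(fits, function(f) ifelse(is.na(f$rel_amp), 0, f$rel_amp), numeric(1))
    amp_pass <- rel >= rel_amp_min
    q <- rep(NA_real_, length(ids))
    q[amp_pass] <- bh_adjust(p[amp_pass])
    sig <- if (sig_mode == "q") !is.na(q) & q < sig_threshold else amp_pass & p < sig_threshold
    out[[as.character(T_h)]] <- data.frame(
      feature_id = ids, period_h = T_h, p = p, q = q,
      mesor = vapply(fits, `[[`, numeric(1), "mesor"),
      amplitude = vapply(fits, `[[`, numeric(1), "amplitude"),
      rel_amp = vapply(fits, function(f) f$rel_amp, numeric(1)),
      phase_h = vapply(fits, function(f) ifelse(is.na(f$peak_phase), NA_real_, f$peak_phase), numeric(1)),
      amp_pass = amp_pass, sig_pass = sig,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
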