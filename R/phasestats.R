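# Circular statistics over peak phases measured in hours on a cycle of
# given period: mean direction, median, dispersion, and a two-cluster
# decomposition of bimodal phase distributions.

#' Circular mean of peak phases
#'
#' Phases are mapped to angles, averaged as unit vectors and mapped
#' back: `mean = atan2(sum sin, sum cos) * T / (2*pi) mod T`. The
#' resultant length `R` in `[0, 1]` measures concentration; when `R` is
#' numerically zero (e.g. antipodal phases) the mean direction is
#' undefined and `NA` is returned with attribute `undefined = TRUE`.
#'
#' @param phases numeric vector of phases in hours, each in `[0, T)`.
#' @param period cycle length T in hours.
#' @return the circular mean in hours, with attribute `R` (resultant
#'   length).
#' @export
circular_mean <- function(phases, period) {
  if (!length(phases)) stop("empty phase set")
  th <- 2 * pi * phases / period
  sn <- mean(sin(th)); cs <- mean(cos(th))
  R <- sqrt(sn^2 + cs^2)
  if (R < 1e-9) {
    out <- NA_real_
    attr(out, "R") <- R
    attr(out, "undefined") <- TRUE
    return(out)
  }
  out <- (atan2(sn, cs) * period / (2 * pi)) %% period
  if (out > period - 1e-9) out <- 0  # wrap the boundary back to 0
  attr(out, "R") <- R
  out
}

#' Circular median of peak phases
#'
#' The observed phase minimising the summed circular distances to all
#' phases; exact ties are broken by the smallest phase value.
#'
#' @inheritParams circular_mean
#' @return the circular median in hours.
#' @export
circular_median <- function(phases, period) {
  if (!length(phases)) stop("empty phase set")
  cand <- sort(unique(phases))
  obj <- vapply(cand, function(c0) sum(phase_difference(rep(c0, length(phases)) %% period,
                                                        phases %% period, period)),
                numeric(1))
  cand[which.min(obj)]  # which.min takes the first, i.e. lowest phase
}

#' Mean circular deviation from the circular mean
#'
#' @inheritParams circular_mean
#' @return mean over phases of the wrapped distance to the circular
#'   mean, in hours; `NA` when the mean direction is undefined.
#' @export
circular_dispersion <- function(phases, period) {
  mu <- circular_mean(phases, period)
  if (is.na(mu)) return(NA_real_)
  mean(phase_difference(phases %% period, rep(as.numeric(mu), length(phases)), period))
}

# angular-deviation style circular SD in hours: sqrt(-2 ln R) * T / 2pi
circular_sd <- function(phases, period) {
  mu <- circular_mean(phases, period)
  R <- attr(mu, "R")
  if (R < 1e-12) return(NA_real_)
  sqrt(-2 * log(R)) * period / (2 * pi)
}

#' Cluster peak phases on the circle
#'
#' k-means on the circle: points are assigned to the centroid with the
#' smallest wrapped distance, centroids are updated by the circular
#' mean, and the algorithm is restarted `n_init` times from seeded
#' rotations of an equispaced (antipodal for k = 2) centroid layout. The
#' best solution by summed within-cluster circular distance is kept. An
#' empty cluster triggers re-initialisation (at most 20 attempts, then
#' an error -- e.g. when all phases coincide and k > 1).
#'
#' @inheritParams circular_mean
#' @param k number of clusters (<= number of phases).
#' @param n_init number of seeded restarts.
#' @param seed integer seed for the restart rotations.
#' @return list: `cluster` (assignments), `centers_h`, `sd_h` (circular
#'   SD per cluster, `sqrt(-2 ln R) * T / 2pi`), `objective` (summed
#'   within-cluster circular distance).
#' @export
phase_clusters <- function(phases, period, k = 2, n_init = 10, seed = 1L) {
  n <- length(phases)
  if (k > n) stop("more clusters than phases")
  if (k == 1) {
    mu <- circular_mean(phases, period)
    return(list(cluster = rep(1L, n), centers_h = as.numeric(mu),
                sd_h = circular_sd(phases, period),
                objective = sum(phase_difference(phases, rep(as.numeric(mu), n), period))))
  }
  run_once <- function(centers) {
    assign_old <- rep(0L, n)
    for (it in 1:100) {
      d <- vapply(seq_len(k), function(j) {
        phase_difference(phases %% period, rep(centers[j], n) %% period, period)
      }, numeric(n))
      d <- matrix(d, nrow = n)
      cl <- max.col(-d, ties.method = "first")
      if (length(unique(cl)) < k) return(NULL)  # empty cluster
      if (all(cl == assign_old)) break
      assign_old <- cl
      centers <- vapply(seq_len(k), function(j) {
        mu <- circular_mean(phases[cl == j], period)
        if (is.na(mu)) return(NA_real_)
        as.numeric(mu)
      }, numeric(1))
      if (anyNA(centers)) return(NULL)
    }
    obj <- sum(d[cbind(seq_len(n), cl)])
    list(cluster = cl, centers = centers %% period, objective = obj)
  }
  best <- NULL
  with_seed(seed, {
    attempts <- 0
    inits <- 0
    while (inits < n_init) {
      rot <- stats::runif(1, 0, period)
      centers <- (rot + (0:(k - 1)) * period / k) %% period
      res <- run_once(centers)
      attempts <- attempts + 1
      if (is.null(res)) {
        if (attempts >= n_init + 20) {
          stop("degenerate clustering: empty cluster in every initialisation")
        }
        next
      }
      inits <- inits + 1
      if (is.null(best) || res$objective < best$objective) best <- res
    }
  })
  sds <- vapply(seq_len(k), function(j) {
    circular_sd(phases[best$cluster == j], period)
  }, numeric(1))
  # order clusters by centre for deterministic labelling
  ord <- order(best$centers)
  relab <- match(best$cluster, ord)
  list(cluster = relab, centers_h = best$centers[ord], sd_h = sds[ord],
       objective = best$objective)
}
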