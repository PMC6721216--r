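# Independent oracles used across tests. These deliberately use plain
# loops and first-principles definitions, not the package's code paths.

# Definitional BH step-up: q(i) = min_{j >= i} p(j) * n / j on sorted p.
bh_bruteforce <- function(p) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in i:n) best <- min(best, ps[j] * n / j)
    q[i] <- min(1, best)
  }
  out <- numeric(n)
  out[ord] <- q
  out
}

# All permutations of 1..n as a list (small n only).
perms_list <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in perms_list(n - 1)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1]] <- append(sub, n, after = pos - 1)
    }
  }
  out
}

# Exhaustive-enumeration umbrella-test p-value, Bonferroni-over-shapes
# form: per candidate peak the summed pair counts along the rising and
# falling arcs are computed by direct loops; the per-shape p is the
# fraction of all value orderings with a statistic at least as large,
# and the final p is min over shapes times the number of shapes.
umbrella_enum_oracle <- function(values, times, period) {
  ph <- round(times %% period, 9)
  ub <- sort(unique(ph))
  bins <- match(ph, ub)
  m <- length(ub)
  pair_count <- function(vals, ga, gb) {
    s <- 0
    for (x in vals[bins == ga]) for (y in vals[bins == gb]) {
      s <- s + (y > x) + 0.5 * (y == x)
    }
    s
  }
  shape_stat <- function(vals, peak) {
    trough <- ((peak - 1 + m %/% 2) %% m) + 1
    rise <- ((trough - 1 + 0:((peak - trough) %% m)) %% m) + 1
    fall <- ((peak - 1 + 0:((trough - peak) %% m)) %% m) + 1
    seen <- matrix(FALSE, m, m)
    s <- 0
    for (i in seq_along(rise)) for (j in seq_along(rise)) if (i < j) {
      a <- rise[i]; b <- rise[j]
      if (!seen[a, b]) { s <- s + pair_count(vals, a, b); seen[a, b] <- TRUE }
    }
    for (i in seq_along(fall)) for (j in seq_along(fall)) if (i < j) {
      a <- fall[j]; b <- fall[i]
      if (!seen[a, b]) { s <- s + pair_count(vals, a, b); seen[a, b] <- TRUE }
    }
    s
  }
  all_p <- perms_list(length(values))
  p_shapes <- numeric(m)
  for (peak in seq_len(m)) {
    obs <- shape_stat(values, peak)
    cnt <- 0
    for (ix in all_p) {
      if (shape_stat(values[ix], peak) >= obs - 1e-12) cnt <- cnt + 1
    }
    p_shapes[peak] <- cnt / length(all_p)
  }
  min(1, min(p_shapes) * m)
}

# One-tailed hypergeometric tail by closed form: P(X >= a) for the 2x2
# table a (pos above), b (pos below), c (ctrl above), d (ctrl below).
hyper_tail_oracle <- function(a, b, c, d) {
  n_pos <- a + b; n_above <- a + c; N <- a + b + c + d
  ks <- a:min(n_pos, n_above)
  sum(choose(n_above, ks) * choose(N - n_above, n_pos - ks)) / choose(N, n_pos)
}

# grid-search circular summaries: the mean direction minimises the
# summed 1 - cos dissimilarity, the median the summed wrapped distance
circ_grid_oracle <- function(phases, period, step = 0.002) {
  grid <- seq(0, period, by = step)
  wrap <- function(d) pmin(abs(d) %% period, period - abs(d) %% period)
  obj_mean <- vapply(grid, function(mu) {
    sum(1 - cos(2 * pi * (phases - mu) / period))
  }, numeric(1))
  obj_med <- vapply(grid, function(mu) sum(wrap(phases - mu)), numeric(1))
  list(mean = grid[which.min(obj_mean)], median = grid[which.min(obj_med)])
}
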