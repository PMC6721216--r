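test_that("quantile normalisation equalises column distributions", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 2,
              dimnames = list(c("p1", "p2", "p3"), NULL))
  tm <- timed_matrix(m, c(0, 2), "log2intensity")
  qn <- quantile_normalize(tm)
  expect_equal(unname(qn$values[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn$values[, 2]), c(2.5, 3.5, 4.5))

  # identical columns are unchanged
  m2 <- matrix(rep(c(4, 1, 7), 3), ncol = 3,
               dimnames = list(c("p1", "p2", "p3"), NULL))
  tm2 <- timed_matrix(m2, c(0, 2, 4), "log2intensity")
  expect_equal(quantile_normalize(tm2)$values, tm2$values)

  # permuting rows of one column leaves the value multiset unchanged
  m3 <- m; m3[, 2] <- m3[c(3, 1, 2), 2]
  tm3 <- timed_matrix(m3, c(0, 2), "log2intensity")
  qn3 <- quantile_normalize(tm3)
  expect_equal(unname(sort(qn3$values[, 2])), unname(sort(qn$values[, 2])))

  # idempotence
  expect_equal(quantile_normalize(qn)$values, qn$values)
})

test_that("median polish matches the reference sweeps", {
  # exactly additive block: zero residuals
  add <- outer(c(0, 1, 3), c(0, 2, 5), `+`) + 10
  mp <- median_polish(add)
  expect_lt(max(abs(mp$residuals)), 1e-10)
  recon <- mp$overall + outer(mp$row, mp$col, `+`) + mp$residuals
  expect_equal(recon, add, tolerance = 1e-12, ignore_attr = TRUE)

  # one perturbed cell: residual mass concentrates there; compare with
  # stats::medpolish as the independent reference implementation
  pert <- add
  pert[2, 2] <- pert[2, 2] + 1
  mp2 <- median_polish(pert, eps = 1e-9, maxiter = 50)
  ref <- stats::medpolish(pert, eps = 1e-9, maxit = 50, trace.iter = FALSE)
  expect_equal(mp2$residuals, ref$residuals, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(which.max(abs(mp2$residuals)), 5L)  # cell (2,2)

  # permuting sample order permutes chip effects, residual multiset fixed
  set.seed(11)
  blk <- matrix(rnorm(8 * 6), 8)
  perm <- c(3, 1, 6, 2, 5, 4)
  mpa <- median_polish(blk)
  mpb <- median_polish(blk[, perm])
  expect_equal(mpb$col, mpa$col[perm], tolerance = 1e-12)
  expect_equal(sort(as.vector(mpb$residuals)), sort(as.vector(mpa$residuals)),
               tolerance = 1e-12)

  expect_error(median_polish(matrix(1:3, 1)), "2 probes")
})

test_that("splicing score follows the run-sum definition", {
  # all-zero residuals score zero (with zero-MAD flag)
  z0 <- matrix(0, 6, 4)
  s0 <- firma_score(z0)
  expect_equal(as.numeric(s0), rep(0, 4))
  expect_true(isTRUE(attr(s0, "zero_mad")))

  # a run of 4 adjacent probes at standardised residual z = 1 scores
  # 4/sqrt(4) = 2 exactly. The surrounding residuals are chosen so the
  # gene MAD is exactly 1 (median 0, median absolute deviation 1/1.4826)
  # and no other run can beat the planted one.
  u <- 1 / 1.4826  # inverse of mad()'s scaling constant
  col1 <- u * c(-1, -1, -1, -1, -1, -1, -1, 1, 1, 1)
  col2 <- c(-u, -u, 1, 1, 1, 1, -u, u, u, u)
  resid <- cbind(col1, col2)
  expect_equal(stats::mad(resid), 1, tolerance = 1e-12)
  sc <- firma_score(resid)
  expect_equal(sc[2], 2, tolerance = 1e-12)

  # brute-force oracle on random residual grids: maximum over all runs
  # of |sum z| / sqrt(length), recomputed by direct loops
  set.seed(14)
  for (rep in 1:10) {
    r <- matrix(rnorm(7 * 5), 7, 5)
    z <- r / stats::mad(r)
    expected <- vapply(1:5, function(j) {
      best <- 0
      for (k in 1:7) for (l in k:7) {
        best <- max(best, abs(sum(z[k:l, j])) / sqrt(l - k + 1))
      }
      best
    }, numeric(1))
    expect_equal(firma_score(r), expected, tolerance = 1e-12)
  }

  # probe_order reorders rows before scoring
  r2 <- matrix(rnorm(12), 6, 2)
  expect_equal(firma_score(r2, probe_order = 6:1),
               firma_score(r2[6:1, , drop = FALSE]), tolerance = 1e-12)

  expect_error(firma_score(matrix(1, 4, 2), probe_order = c(1, 1, 2, 3)),
               "probe_order")
})

test_that("score is invariant to per-sample and per-probe constants via the polish", {
  set.seed(12)
  des <- probe_design(1, probes_per_gene = 8, sampling_times = seq(0, 22, 2),
                      noise_sd = 0.2, seed = 13)
  pm <- gen_probe_matrix(des)
  block <- pm$intensities$values
  # per-probe (row) constants are absorbed exactly by the first row sweep
  s1 <- firma_score(median_polish(block)$residuals)
  row_shift <- sweep(block, 1, rnorm(nrow(block), 0, 2), `+`)
  expect_equal(firma_score(median_polish(row_shift)$residuals), s1,
               tolerance = 1e-12)
  # per-sample (column) constants are absorbed over the sweeps; run the
  # polish to tight convergence since the decomposition is iterative
  col_shift <- sweep(block, 2, rnorm(ncol(block), 0, 3), `+`)
  s2 <- firma_score(median_polish(col_shift, eps = 1e-10, maxiter = 100)$residuals)
  s1t <- firma_score(median_polish(block, eps = 1e-10, maxiter = 100)$residuals)
  expect_equal(s2, s1t, tolerance = 0.05)
})

test_that("score grows with event depth", {
  # a short affected run (2 of 8 probes) keeps the gene's residual MAD
  # noise-dominated, so deeper events give larger standardised scores
  depths <- c(0.25, 0.5, 1.0, 2.0)
  peak_score <- vapply(depths, function(d) {
    des <- probe_design(1, probes_per_gene = 8,
                        sampling_times = seq(0, 46, 2),
                        events = data.frame(gene_id = "g0001",
                                            probe_start = 3, probe_end = 4,
                                            period = 24, phase = 0, depth = d),
                        noise_sd = 0.15, seed = 21)
    pm <- gen_probe_matrix(des)
    mp <- median_polish(pm$intensities$values)
    max(firma_score(mp$residuals))
  }, numeric(1))
  expect_true(all(diff(peak_score) > 0))
})

test_that("the scan flags planted events but not whole-gene rhythms", {
  ev <- data.frame(gene_id = sprintf("g%04d", 1:3), probe_start = 3,
                   probe_end = 6, period = 24, phase = 8, depth = 1.0)
  des <- probe_design(8, probes_per_gene = 8, sampling_times = seq(0, 46, 2),
                      events = ev, noise_sd = 0.15, seed = 31)
  pm <- gen_probe_matrix(des)
  scan <- rhythmic_splicing_scan(pm$intensities, pm$annotation)
  hit <- scan$rhythms$feature_id[scan$rhythms$sig_pass]
  expect_true(all(ev$gene_id %in% hit))

  # whole-gene expression rhythm, no differential probe run: the chip
  # effect absorbs it and nothing is flagged
  des0 <- probe_design(8, probes_per_gene = 8,
                       sampling_times = seq(0, 46, 2),
                       chip_rhythm = list(amp = 1.5, period = 24, phase = 4),
                       noise_sd = 0.15, seed = 32)
  pm0 <- gen_probe_matrix(des0)
  scan0 <- rhythmic_splicing_scan(pm0$intensities, pm0$annotation)
  expect_lte(sum(scan0$rhythms$sig_pass), 1)

  # genes with fewer than 4 probes are skipped with a warning
  ann_small <- pm$annotation
  ann_small <- ann_small[!(ann_small$gene_id == "g0008" &
                             ann_small$probe_index > 3), ]
  tm_small <- timed_matrix(pm$intensities$values[ann_small$probe_id, ],
                           pm$intensities$sample_times, "log2intensity")
  expect_warning(rhythmic_splicing_scan(tm_small, ann_small), "skipped")
})
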