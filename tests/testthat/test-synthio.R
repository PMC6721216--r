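test_that("flat generator gives time-constant expected counts and seed determinism", {
  des <- counts_design(4, seq(0, 22, 2), tx_per_gene = 2, dispersion = 0,
                       library_sizes = 1e6, seed = 42)
  sim1 <- gen_transcript_counts(des)
  sim2 <- gen_transcript_counts(des)
  expect_identical(sim1$counts$values, sim2$counts$values)
  # dispersion 0, rel_amp 0, equal libraries: Poisson draws around a
  # constant mean of 100 per transcript and time point
  means <- rowMeans(sim1$counts$values)
  expect_true(all(abs(means - 100) < 4 * sqrt(100 / 12)))
})

test_that("noise-free mean profile peaks at the planted phase", {
  des <- counts_design(1, seq(0, 46, 2), tx_per_gene = 1, dispersion = 0,
                       library_sizes = 1e6, seed = 5)
  truth <- rhythm_truth(des$tx2gene$tx_id, period = 24, peak_phase = 6,
                        rel_amp = 0.5, baseline = 1e5)
  sim <- gen_transcript_counts(des, truth)
  prof <- sim$counts$values[1, ]
  peaks <- des$sampling_times[prof == max(prof)] %% 24
  expect_true(all(abs(peaks - 6) <= 1)) # within grid resolution
})

test_that("truth validation rejects impossible rhythms", {
  expect_error(rhythm_truth("t1", period = 24, peak_phase = 3, rel_amp = 1,
                            baseline = 10), "rel_amp")
  expect_error(rhythm_truth("t1", rel_amp = 0, baseline = -1), "baseline")
  expect_error(rhythm_truth("t1", period = 24, peak_phase = 25,
                            rel_amp = 0.3, baseline = 10), "peak_phase")
  des <- counts_design(1, seq(0, 22, 2), tx_per_gene = 1, seed = 1)
  expect_error(
    gen_transcript_counts(des, rhythm_truth("nope", period = 24,
                                            peak_phase = 0, rel_amp = 0.2,
                                            baseline = 10)),
    "not present"
  )
})

test_that("gene aggregation sums transcripts and cancels antiphasic pairs", {
  # exact cancellation needs the noise-free generator
  des <- counts_design(1, seq(0, 46, 2), tx_per_gene = 2, dispersion = 0,
                       seed = 9)
  truth <- rhythm_truth(des$tx2gene$tx_id, period = c(24, 24),
                        peak_phase = c(6, 18), rel_amp = c(0.5, 0.5),
                        baseline = c(1e5, 1e5))
  sim <- gen_transcript_counts(des, truth)
  g <- gen_gene_counts(sim$counts, sim$tx2gene)
  prof <- g$values[1, ]
  # Poisson noise around the flat 2e5 sum: relative spread is tiny
  expect_lt(stats::sd(prof) / mean(prof), 0.01)

  # single-transcript gene: gene row equals transcript row
  des1 <- counts_design(1, seq(0, 22, 2), tx_per_gene = 1, seed = 2)
  sim1 <- gen_transcript_counts(des1)
  g1 <- gen_gene_counts(sim1$counts, sim1$tx2gene)
  expect_equal(unname(g1$values[1, ]), unname(sim1$counts$values[1, ]))

  # three flat transcripts, baselines 10/20/30: expected gene baseline 60
  des3 <- counts_design(1, seq(0, 22, 2), tx_per_gene = 3, dispersion = 0,
                        seed = 3)
  truth3 <- rhythm_truth(des3$tx2gene$tx_id, baseline = c(10, 20, 30) * 1e3)
  sim3 <- gen_transcript_counts(des3, truth3)
  g3 <- gen_gene_counts(sim3$counts, sim3$tx2gene)
  expect_lt(abs(mean(g3$values[1, ]) - 6e4) / 6e4, 0.01)

  # column sums conserved
  expect_equal(colSums(g3$values), colSums(sim3$counts$values),
               ignore_attr = TRUE)

  # unmapped transcript errors
  bad_map <- sim3$tx2gene[-1, ]
  expect_error(gen_gene_counts(sim3$counts, bad_map), "unmapped")
})

test_that("probe matrix is additive without noise and encodes events exactly", {
  des <- probe_design(3, probes_per_gene = 6, sampling_times = seq(0, 22, 2),
                      noise_sd = 0, seed = 7)
  pm <- gen_probe_matrix(des)
  # no noise, no events, no chip rhythm: constant over time per probe
  expect_true(all(apply(pm$intensities$values, 1, stats::sd) < 1e-12))

  ev <- data.frame(gene_id = "g0001", probe_start = 2, probe_end = 5,
                   period = 24, phase = 6, depth = 1.0)
  des2 <- probe_design(3, probes_per_gene = 6,
                       sampling_times = seq(0, 22, 2), events = ev,
                       noise_sd = 0, seed = 7)
  pm2 <- gen_probe_matrix(des2)
  aff <- pm2$annotation$gene_id == "g0001" &
    pm2$annotation$probe_index %in% 2:5
  unaff <- pm2$annotation$gene_id == "g0001" & !pm2$annotation$probe_index %in% 2:5
  diffprof <- colMeans(pm2$intensities$values[aff, ]) -
    colMeans(pm2$intensities$values[unaff, ])
  t_h <- des2$sampling_times
  expected <- 1.0 * cos(2 * pi * (t_h - 6) / 24)
  expect_equal(unname(diffprof - mean(diffprof)),
               expected - mean(expected), tolerance = 1e-10)

  pm2b <- gen_probe_matrix(des2)
  expect_identical(pm2$intensities$values, pm2b$intensities$values)

  expect_error(probe_design(2, probes_per_gene = 4,
                            events = data.frame(gene_id = "g0001",
                                                probe_start = 1,
                                                probe_end = 5, period = 24,
                                                phase = 0, depth = 1)),
               "probe runs")
})

test_that("promoter generator respects GC, plant rate and determinism", {
  motif <- pssm(matrix(c(0.97, 0.01, 0.01, 0.01), 4, 6), "polyA")
  p0 <- gen_promoters(10, 10, length = 80, gc_pos = 0.6, gc_neg = 0.4,
                      motif = motif, plant_rate = 0, seed = 3)
  expect_true(all(!p0$truth$planted))
  expect_lt(abs(mean(gc_content(p0$positives)) - 0.6), 0.08)
  expect_lt(abs(mean(gc_content(p0$negatives)) - 0.4), 0.08)

  p1 <- gen_promoters(5, 2, length = 6, gc_pos = 0.5, gc_neg = 0.5,
                      motif = motif, plant_rate = 1, seed = 4)
  expect_true(all(p1$truth$planted))
  expect_true(all(p1$truth$position == 1))
  # plant_rate 1 at length == width: sequences are pure motif samples
  expect_true(all(grepl("^A{4,}", p1$positives) |
                    vapply(strsplit(p1$positives, ""),
                           function(b) mean(b == "A") >= 0.5, logical(1))))

  pg <- gen_promoters(3, 3, length = 40, gc_pos = 1, gc_neg = 0.5, seed = 5)
  expect_equal(gc_content(pg$positives), rep(1, 3))

  p1b <- gen_promoters(5, 2, length = 6, gc_pos = 0.5, gc_neg = 0.5,
                       motif = motif, plant_rate = 1, seed = 4)
  expect_identical(p1$positives, p1b$positives)

  expect_error(gen_promoters(2, 2, length = 4, gc_pos = 0.5, gc_neg = 0.5,
                             motif = motif, plant_rate = 1, seed = 1),
               "wider")
})

test_that("timed matrix TSV round-trips", {
  des <- counts_design(3, seq(0, 30, 3), tx_per_gene = 1, seed = 6)
  sim <- gen_transcript_counts(des)
  path <- tempfile(fileext = ".tsv")
  write_timed_matrix(sim$counts, path)
  back <- read_timed_matrix(path)
  expect_equal(back$values, sim$counts$values)
  expect_equal(back$sample_times, sim$counts$sample_times)
  expect_equal(back$units, "counts")
})
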