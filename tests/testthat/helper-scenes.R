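# Shared scene builders for tests.

# Scenes keep planted features at moderate CPM (log2-CPM mesor ~6) by
# routing most of the library through a flat background transcript, as
# in real libraries where any one transcript is a small fraction of the
# reads. This matters because the relative-amplitude filter divides the
# fitted amplitude by the log2-CPM mesor.
BG_BASELINE <- 1e6

# Two equal-baseline antiphasic transcripts of one gene plus a flat
# transcript of a second gene and the background transcript; the
# antiphasic pair cancels exactly in the gene-level sum.
antiphasic_scene <- function(seed, sampling_times = seq(0, 46, 2),
                             rel_amp = 0.6, dispersion = 0.005,
                             baseline = 50) {
  des <- counts_design(3, sampling_times, tx_per_gene = c(2, 1, 1),
                       dispersion = dispersion, seed = seed)
  truth <- rhythm_truth(
    des$tx2gene$tx_id,
    period = c(24, 24, NA, NA),
    peak_phase = c(6, 18, NA, NA),
    rel_amp = c(rel_amp, rel_amp, 0, 0),
    baseline = c(baseline, baseline, baseline, BG_BASELINE)
  )
  sim <- gen_transcript_counts(des, truth)
  list(sim = sim, gene = gen_gene_counts(sim$counts, sim$tx2gene),
       tx2gene = sim$tx2gene)
}

# n_pairs two-transcript genes whose isoforms are separated by dphi
# hours at the given period, equal relative amplitude, plus the flat
# background transcript.
pair_scene <- function(seed, n_pairs, dphi, sampling_times = seq(0, 22, 2),
                       period = 24, rel_amp = 0.6, dispersion = 0.005,
                       baseline = 50) {
  des <- counts_design(n_pairs + 1, sampling_times,
                       tx_per_gene = c(rep(2, n_pairs), 1),
                       dispersion = dispersion, seed = seed)
  phases <- with_seed_helper(seed + 7, stats::runif(n_pairs, 0, period))
  t2g <- des$tx2gene
  is_bg <- t2g$gene_id == t2g$gene_id[nrow(t2g)]
  first <- !duplicated(t2g$gene_id) & !is_bg
  phase <- rep(NA_real_, nrow(t2g))
  phase[first] <- phases
  phase[!first & !is_bg] <- (phases + dphi) %% period
  truth <- rhythm_truth(
    t2g$tx_id,
    period = ifelse(is_bg, NA, period),
    peak_phase = phase,
    rel_amp = ifelse(is_bg, 0, rel_amp),
    baseline = ifelse(is_bg, BG_BASELINE, baseline)
  )
  sim <- gen_transcript_counts(des, truth)
  list(sim = sim, tx2gene = t2g, phases_a = phases)
}

with_seed_helper <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# log2 CPM pipeline shorthand used by several tests
norm_log_cpm <- function(counts_tm) {
  f <- tmm_factors(counts_tm)
  log_cpm(counts_tm, f)
}
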