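# Small frozen demonstration scenes. Every scene is generated from a
# registered seed and written as plain-text files plus a digest table,
# so regeneration can be checked byte-for-byte.

fixture_registry <- list(
  masking_demo = list(
    seed = 101L,
    description = "two antiphasic equal-amplitude transcripts whose gene-level sum is flat, plus a gene rhythmic only in aggregate"
  ),
  phase_bimodal = list(
    seed = 202L,
    description = "peak phases drawn around 6 h and 18 h, two circular clusters"
  ),
  splicing_event = list(
    seed = 303L,
    description = "probe-level arrays with one 24-h rhythmic exon-inclusion event"
  ),
  promoter_motifs = list(
    seed = 404L,
    description = "GC-biased promoter sets with a planted clock-box-like motif"
  )
)

#' List available fixture scenes
#' @return data.frame `name`, `seed`, `description`.
#' @export
list_fixtures <- function() {
  data.frame(name = names(fixture_registry),
             seed = vapply(fixture_registry, `[[`, integer(1), "seed"),
             description = vapply(fixture_registry, `[[`, character(1), "description"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Materialise a fixture scene on disk
#'
#' Writes the scene's files plus a `digests.tsv` (file name, md5) into
#' `dir`. Regenerating a scene reproduces its digests exactly.
#'
#' @param name registered scene name (see [list_fixtures()]).
#' @param dir output directory (created if needed).
#' @return data.frame of file digests, invisibly.
#' @export
make_fixture <- function(name, dir) {
  if (!name %in% names(fixture_registry)) {
    stop("unknown fixture: ", name, " (see list_fixtures())")
  }
  seed <- fixture_registry[[name]]$seed
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- switch(
    name,
    masking_demo = {
      sc <- masking_scene(seed)
      write_timed_matrix(sc$tx, file.path(dir, "transcript_counts.tsv"))
      write_timed_matrix(sc$gene, file.path(dir, "gene_counts.tsv"))
      write_tsv(sc$tx2gene, file.path(dir, "tx2gene.tsv"))
      c("transcript_counts.tsv", "gene_counts.tsv", "tx2gene.tsv")
    },
    phase_bimodal = {
      ph <- bimodal_phases(seed)
      write_tsv(data.frame(feature_id = sprintf("f%03d", seq_along(ph)),
                           phase_h = round(ph, 6)),
                file.path(dir, "phases.tsv"))
      "phases.tsv"
    },
    splicing_event = {
      des <- probe_design(
        n_genes = 12, probes_per_gene = 8,
        sampling_times = seq(0, 46, 2),
        events = data.frame(gene_id = "g0001", probe_start = 3, probe_end = 6,
                            period = 24, phase = 8, depth = 1.0),
        noise_sd = 0.15, seed = seed
      )
      pm <- gen_probe_matrix(des)
      write_timed_matrix(pm$intensities, file.path(dir, "probe_intensities.tsv"))
      write_tsv(pm$annotation, file.path(dir, "probe_annotation.tsv"))
      write_tsv(pm$events, file.path(dir, "event_truth.tsv"))
      c("probe_intensities.tsv", "probe_annotation.tsv", "event_truth.tsv")
    },
    promoter_motifs = {
      motif <- demo_motif()
      prom <- gen_promoters(n_pos = 20, n_neg = 20, length = 200,
                            gc_pos = 0.6, gc_neg = 0.4, motif = motif,
                            plant_rate = 1, seed = seed)
      write_fasta(prom$positives, file.path(dir, "positives.fa"))
      write_fasta(prom$negatives, file.path(dir, "controls.fa"))
      write_meme(list(motif), file.path(dir, "motif.meme"))
      write_tsv(prom$truth, file.path(dir, "plant_truth.tsv"))
      c("positives.fa", "controls.fa", "motif.meme", "plant_truth.tsv")
    }
  )
  digests <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(dir, files))),
    stringsAsFactors = FALSE
  )
  write_tsv(digests, file.path(dir, "digests.tsv"))
  invisible(digests)
}

# Scene: gene 1 has two equal-baseline antiphasic transcripts (masked
# at gene level); gene 2 has three flat transcripts; gene 3 has one
# rhythmic transcript (rhythmic at both levels); gene 4 is a flat
# background transcript carrying most of the library, which keeps the
# focal features at moderate CPM as in a real library.
masking_scene <- function(seed = 101L, sampling_times = seq(0, 46, 2),
                          rel_amp = 0.5, noise_dispersion = 0.02) {
  des <- counts_design(4, sampling_times, tx_per_gene = c(2, 3, 1, 1),
                       dispersion = noise_dispersion, seed = seed)
  truth <- rhythm_truth(
    feature_id = des$tx2gene$tx_id,
    period = c(24, 24, NA, NA, NA, 24, NA),
    peak_phase = c(6, 18, NA, NA, NA, 3, NA),
    rel_amp = c(rel_amp, rel_amp, 0, 0, 0, rel_amp, 0),
    baseline = c(60, 60, 40, 50, 60, 80, 1e6)
  )
  sim <- gen_transcript_counts(des, truth)
  gene <- gen_gene_counts(sim$counts, sim$tx2gene)
  list(tx = sim$counts, gene = gene, tx2gene = sim$tx2gene, truth = sim$truth)
}

bimodal_phases <- function(seed = 202L, n = 60, centers = c(6, 18),
                           sd = 0.5, period = 24) {
  with_seed(seed, {
    grp <- sample(1:2, n, replace = TRUE, prob = c(2 / 3, 1 / 3))
    (centers[grp] + stats::rnorm(n, 0, sd)) %% period
  })
}

# small high-information palindromic-ish motif used by fixtures and docs
demo_motif <- function() {
  core <- c("T", "T", "A", "T", "G", "T", "A", "A")
  mat <- matrix(0.04, nrow = 4, ncol = length(core),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(core)) mat[core[j], j] <- 0.88
  pssm(mat, motif_id = "dbox_like")
}
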