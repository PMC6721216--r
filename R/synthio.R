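# Synthetic time-course generators with machine-readable ground truth.
# Designs emulate dense circadian sampling: 2-h steps over 48 h (array),
# 2-h steps over 24 h, and 3-h steps over 30 h (cell-culture RNA-seq).

# Run `expr` with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards. All generators route randomness through
# this so identical seeds give bit-identical output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

#' Sampling-design description for synthetic transcript counts
#'
#' @param n_genes number of genes.
#' @param sampling_times strictly increasing vector of sampling hours, e.g.
#'   `seq(0, 46, 2)` (48-h series at 2-h steps), `seq(0, 22, 2)` (24-h
#'   series) or `seq(0, 30, 3)` (30-h series).
#' @param tx_per_gene either a fixed integer, an integer vector of length
#'   `n_genes`, or the default `NULL`, which draws per-gene transcript
#'   numbers from a truncated geometric distribution on 1..18 with mean
#'   about 1.7 expressed transcripts per gene.
#' @param dispersion negative-binomial dispersion (>= 0; 0 means Poisson).
#' @param library_sizes per-sample library sizes (> 0); a single value is
#'   recycled.
#' @param seed integer seed driving all randomness of the design.
#' @return a `counts_design` list, including the realised `tx2gene` map
#'   (columns `tx_id`, `gene_id`).
#' @export
counts_design <- function(n_genes,
                          sampling_times,
                          tx_per_gene = NULL,
                          dispersion = 0.05,
                          library_sizes = 1e6,
                          seed = 1L) {
  stopifnot(n_genes >= 1, length(sampling_times) >= 2)
  if (any(diff(sampling_times) <= 0)) {
    stop("sampling_times must be strictly increasing")
  }
  if (dispersion < 0) stop("dispersion must be >= 0")
  library_sizes <- rep_len(as.numeric(library_sizes), length(sampling_times))
  if (any(library_sizes <= 0)) stop("all library sizes must be > 0")

  ntx <- with_seed(seed, {
    if (is.null(tx_per_gene)) {
      # truncated geometric on 1..18, success prob tuned to mean ~1.7
      k <- 1:18
      pr <- 0.588 * (1 - 0.588)^(k - 1)
      sample(k, n_genes, replace = TRUE, prob = pr / sum(pr))
    } else {
      rep_len(as.integer(tx_per_gene), n_genes)
    }
  })
  if (any(ntx < 1) || any(ntx > 18)) stop("transcripts per gene must be in 1..18")
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  tx2gene <- data.frame(
    tx_id = unlist(lapply(seq_len(n_genes),
                          function(i) sprintf("%s.t%d", gene_ids[i], seq_len(ntx[i])))),
    gene_id = rep(gene_ids, ntx),
    stringsAsFactors = FALSE
  )
  structure(
    list(n_genes = n_genes, sampling_times = as.numeric(sampling_times),
         dispersion = dispersion, library_sizes = library_sizes,
         seed = as.integer(seed), tx2gene = tx2gene),
    class = "counts_design"
  )
}

#' Ground-truth rhythm table for a set of features
#'
#' One row per feature: `period` (hours, `NA` for arrhythmic features),
#' `peak_phase` (hours in `[0, period)`), `rel_amp` (relative amplitude
#' rho in `[0, 1)` on the linear scale) and `baseline` (linear-scale mean).
#' `rel_amp` is 0 exactly when `period` is `NA`; `peak_phase` is only
#' defined where `rel_amp > 0`.
#'
#' @param feature_id character vector of feature ids.
#' @param period,peak_phase,rel_amp,baseline numeric vectors recycled to
#'   the length of `feature_id`.
#' @return a validated `data.frame` (class `rhythm_truth`).
#' @export
rhythm_truth <- function(feature_id, period = NA_real_, peak_phase = NA_real_,
                         rel_amp = 0, baseline = 100) {
  n <- length(feature_id)
  df <- data.frame(
    feature_id = as.character(feature_id),
    period = rep_len(as.numeric(period), n),
    peak_phase = rep_len(as.numeric(peak_phase), n),
    rel_amp = rep_len(as.numeric(rel_amp), n),
    baseline = rep_len(as.numeric(baseline), n),
    stringsAsFactors = FALSE
  )
  if (any(df$baseline <= 0)) stop("baseline must be > 0")
  if (any(df$rel_amp < 0 | df$rel_amp >= 1)) {
    stop("rel_amp must lie in [0, 1): the modulated mean must stay positive")
  }
  rhythmic <- df$rel_amp > 0
  if (any(rhythmic & is.na(df$period))) stop("rhythmic features need a period")
  if (any(!rhythmic & !is.na(df$period))) {
    stop("rel_amp must be 0 exactly when period is NA")
  }
  if (any(rhythmic & (is.na(df$peak_phase) |
                      df$peak_phase < 0 | df$peak_phase >= df$period))) {
    stop("peak_phase must lie in [0, period) for rhythmic features")
  }
  class(df) <- c("rhythm_truth", "data.frame")
  df
}

#' Draw a random ground-truth table for a counts design
#'
#' Convenience scene builder: a fraction of transcripts is made rhythmic
#' with uniformly distributed peak phases and log-normal baselines.
#'
#' @param design a [counts_design()].
#' @param frac_rhythmic fraction of transcripts carrying a rhythm.
#' @param periods candidate periods (hours) sampled uniformly for rhythmic
#'   transcripts.
#' @param rel_amp_range range of linear-scale relative amplitudes.
#' @param baseline_meanlog,baseline_sdlog log-normal baseline parameters.
#' @return a [rhythm_truth()] table covering every transcript in the design.
#' @export
sample_truth <- function(design, frac_rhythmic = 0.2, periods = c(24, 12),
                         rel_amp_range = c(0.2, 0.8),
                         baseline_meanlog = log(100), baseline_sdlog = 1) {
  tx <- design$tx2gene$tx_id
  with_seed(design$seed + 1L, {
    n <- length(tx)
    rhythmic <- stats::runif(n) < frac_rhythmic
    per <- ifelse(rhythmic, sample(rep_len(periods, 2), n, replace = TRUE), NA)
    rho <- ifelse(rhythmic,
                  stats::runif(n, rel_amp_range[1], rel_amp_range[2]), 0)
    phase <- rep(NA_real_, n)
    phase[rhythmic] <- stats::runif(sum(rhythmic)) * per[rhythmic]
    rhythm_truth(tx, period = per, peak_phase = phase, rel_amp = rho,
                 baseline = stats::rlnorm(n, baseline_meanlog, baseline_sdlog))
  })
}

#' Generate transcript-level counts with planted rhythms
#'
#' The linear-scale mean of transcript i at time t is
#' `baseline * (1 + rel_amp * cos(2*pi*(t - peak_phase)/period))`, scaled
#' per sample by `library_size / mean(library_sizes)`. Counts are drawn
#' negative-binomially with the design's dispersion (Poisson at
#' dispersion 0). Identical seeds give bit-identical output.
#'
#' @param design a [counts_design()].
#' @param truth a [rhythm_truth()] table whose feature ids all match
#'   transcripts of the design (transcripts absent from `truth` default to
#'   flat with baseline 100).
#' @return list with `counts` (`timed_matrix`, units counts), `truth`
#'   (the full per-transcript truth table) and `tx2gene`.
#' @export
gen_transcript_counts <- function(design, truth = NULL) {
  stopifnot(inherits(design, "counts_design"))
  tx <- design$tx2gene$tx_id
  if (is.null(truth)) truth <- rhythm_truth(tx)
  if (!inherits(truth, "rhythm_truth")) {
    truth <- do.call(rhythm_truth, as.list(truth))
  }
  unknown <- setdiff(truth$feature_id, tx)
  if (length(unknown)) {
    stop("truth features not present in the design: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  full <- rhythm_truth(tx)
  idx <- match(truth$feature_id, tx)
  full[idx, ] <- truth
  t_h <- design$sampling_times
  mod <- matrix(1, nrow = length(tx), ncol = length(t_h))
  rhy <- which(full$rel_amp > 0)
  for (i in rhy) {
    mod[i, ] <- 1 + full$rel_amp[i] *
      cos(2 * pi * (t_h - full$peak_phase[i]) / full$period[i])
  }
  scale <- design$library_sizes / mean(design$library_sizes)
  mu <- sweep(full$baseline * mod, 2, scale, `*`)
  counts <- with_seed(design$seed, {
    n <- length(mu)
    draws <- if (design$dispersion == 0) {
      stats::rpois(n, lambda = as.vector(mu))
    } else {
      stats::rnbinom(n, mu = as.vector(mu), size = 1 / design$dispersion)
    }
    matrix(draws, nrow = nrow(mu))
  })
  dimnames(counts) <- list(tx, make.unique(sprintf("ZT%02g", t_h), sep = "_"))
  list(counts = timed_matrix(counts, t_h, "counts"),
       truth = full, tx2gene = design$tx2gene)
}

#' Aggregate transcript counts to gene level
#'
#' Gene count = sum of its transcripts' counts per sample (linear scale).
#' Summing phase-shifted isoforms on the linear scale is what produces
#' gene-level masking: two equal-baseline, equal-amplitude antiphasic
#' transcripts cancel exactly to a flat gene profile.
#'
#' @param tx_counts transcript-level `timed_matrix` (units counts).
#' @param tx2gene data.frame with columns `tx_id`, `gene_id`; every
#'   transcript in the matrix must be mapped exactly once.
#' @return gene-level `timed_matrix` (units counts), genes sorted by id.
#' @export
gen_gene_counts <- function(tx_counts, tx2gene) {
  stopifnot(inherits(tx_counts, "timed_matrix"), tx_counts$units == "counts")
  ids <- feature_ids(tx_counts)
  m <- match(ids, tx2gene$tx_id)
  if (anyNA(m)) {
    stop("unmapped transcript ids: ",
         paste(utils::head(ids[is.na(m)], 5), collapse = ", "))
  }
  if (anyDuplicated(tx2gene$tx_id)) stop("transcripts mapped more than once")
  g <- rowsum(tx_counts$values, group = tx2gene$gene_id[m], reorder = TRUE)
  timed_matrix(g, tx_counts$sample_times, "counts")
}

#' Probe-level array design with optional splicing events
#'
#' @param n_genes number of genes (probe sets).
#' @param probes_per_gene probes per gene (>= 4).
#' @param sampling_times sampling hours (one array per time point).
#' @param events `NULL` or a data.frame with columns `gene_id`,
#'   `probe_start`, `probe_end` (contiguous affected run, 1-based,
#'   strictly inside `1..probes_per_gene`), `period`, `phase`, `depth`
#'   (log2 units).
#' @param noise_sd Gaussian noise SD in log2 units.
#' @param chip_rhythm `NULL`, or `list(amp=, period=, phase=)` giving every
#'   gene's expression level a shared rhythm over time; used to verify the
#'   splicing score ignores whole-gene expression rhythms.
#' @param seed integer seed.
#' @return a `probe_design` list.
#' @export
probe_design <- function(n_genes, probes_per_gene = 8,
                         sampling_times = seq(0, 46, by = 2),
                         events = NULL, noise_sd = 0.2,
                         chip_rhythm = NULL, seed = 1L) {
  stopifnot(probes_per_gene >= 4, n_genes >= 1)
  if (!is.null(events) && nrow(events)) {
    ok <- events$probe_start >= 1 & events$probe_end <= probes_per_gene &
      events$probe_start <= events$probe_end
    if (!all(ok)) stop("event probe runs must be contiguous and inside 1..probes_per_gene")
    if ((max(events$probe_end - events$probe_start) + 1) > probes_per_gene) {
      stop("event run longer than probe count")
    }
  }
  structure(
    list(n_genes = n_genes, probes_per_gene = probes_per_gene,
         sampling_times = as.numeric(sampling_times), events = events,
         noise_sd = noise_sd, chip_rhythm = chip_rhythm,
         seed = as.integer(seed)),
    class = "probe_design"
  )
}

#' Generate a probe-level log2 intensity matrix
#'
#' `log2 intensity = expression level(t) + probe affinity + event term +
#' Gaussian noise`, where the event term adds
#' `depth * cos(2*pi*(t - phase)/period)` only on the affected probe run.
#'
#' @param design a [probe_design()].
#' @return list with `intensities` (probe-level `timed_matrix`, units
#'   log2intensity), `annotation` (probe_id, gene_id, probe_index) and
#'   `events` (the planted event truth, possibly `NULL`).
#' @export
gen_probe_matrix <- function(design) {
  stopifnot(inherits(design, "probe_design"))
  P <- design$probes_per_gene
  t_h <- design$sampling_times
  genes <- sprintf("g%04d", seq_len(design$n_genes))
  ann <- data.frame(
    probe_id = sprintf("%s.p%02d", rep(genes, each = P), rep(seq_len(P), design$n_genes)),
    gene_id = rep(genes, each = P),
    probe_index = rep(seq_len(P), design$n_genes),
    stringsAsFactors = FALSE
  )
  vals <- with_seed(design$seed, {
    base <- stats::rnorm(design$n_genes, mean = 8, sd = 1)  # per-gene level
    affinity <- stats::rnorm(nrow(ann), mean = 0, sd = 1)   # per-probe effect
    expr <- matrix(rep(base, each = P), nrow = nrow(ann), ncol = length(t_h))
    if (!is.null(design$chip_rhythm)) {
      cr <- design$chip_rhythm
      expr <- expr + matrix(
        cr$amp * cos(2 * pi * (t_h - cr$phase) / cr$period),
        nrow = nrow(ann), ncol = length(t_h), byrow = TRUE
      )
    }
    out <- expr + affinity
    ev <- design$events
    if (!is.null(ev) && nrow(ev)) {
      for (k in seq_len(nrow(ev))) {
        rows <- which(ann$gene_id == ev$gene_id[k] &
                        ann$probe_index >= ev$probe_start[k] &
                        ann$probe_index <= ev$probe_end[k])
        if (!length(rows)) stop("event gene not in design: ", ev$gene_id[k])
        term <- ev$depth[k] * cos(2 * pi * (t_h - ev$phase[k]) / ev$period[k])
        out[rows, ] <- out[rows, ] + matrix(term, length(rows), length(t_h), byrow = TRUE)
      }
    }
    if (design$noise_sd > 0) {
      out <- out + matrix(stats::rnorm(length(out), 0, design$noise_sd), nrow(out))
    }
    out
  })
  dimnames(vals) <- list(ann$probe_id, make.unique(sprintf("ZT%02g", t_h), sep = "_"))
  list(intensities = timed_matrix(vals, t_h, "log2intensity"),
       annotation = ann, events = design$events)
}

#' Generate promoter-like sequence sets with planted motif occurrences
#'
#' Background bases are i.i.d. with the set's GC fraction; each positive
#' sequence carries one motif occurrence sampled column-wise from the PSSM
#' at a uniformly chosen position with probability `plant_rate`. Negatives
#' never carry a planted occurrence.
#'
#' @param n_pos,n_neg numbers of positive and control sequences.
#' @param length sequence length in bp (>= motif width).
#' @param gc_pos,gc_neg GC fractions in (0, 1).
#' @param motif a [pssm()] object, or `NULL` for no planting.
#' @param plant_rate probability in `[0, 1]` that a positive carries the
#'   motif.
#' @param seed integer seed.
#' @return list with `positives`, `negatives` (named character vectors)
#'   and `truth` (data.frame seq_id, planted, position).
#' @export
gen_promoters <- function(n_pos, n_neg, length = 500, gc_pos = 0.5,
                          gc_neg = 0.5, motif = NULL, plant_rate = 0,
                          seed = 1L) {
  stopifnot(gc_pos > 0, gc_pos <= 1, gc_neg > 0, gc_neg <= 1,
            plant_rate >= 0, plant_rate <= 1)
  W <- if (is.null(motif)) 0L else ncol(motif$mat)
  if (length < W) stop("motif wider than sequence")
  draw_set <- function(n, gc, prefix) {
    pr <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    vapply(seq_len(n), function(i) {
      paste(sample(names(pr), length, replace = TRUE, prob = pr), collapse = "")
    }, character(1))
  }
  with_seed(seed, {
    pos <- draw_set(n_pos, gc_pos)
    neg <- draw_set(n_neg, gc_neg)
    names(pos) <- sprintf("pos%03d", seq_len(n_pos))
    names(neg) <- sprintf("neg%03d", seq_len(n_neg))
    truth <- data.frame(seq_id = names(pos), planted = FALSE,
                        position = NA_integer_, stringsAsFactors = FALSE)
    if (!is.null(motif) && plant_rate > 0) {
      for (i in seq_len(n_pos)) {
        if (stats::runif(1) <= plant_rate) {
          occ <- paste(vapply(seq_len(W), function(w) {
            sample(rownames(motif$mat), 1, prob = motif$mat[, w])
          }, character(1)), collapse = "")
          at <- if (length == W) 1L else sample.int(length - W + 1L, 1)
          substr(pos[i], at, at + W - 1L) <- occ
          truth$planted[i] <- TRUE
          truth$position[i] <- at
        }
      }
    }
    list(positives = pos, negatives = neg, truth = truth)
  })
}
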