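# Promoter windows, GC content, rank-sum comparison of gene sets, and
# clock-motif enrichment by average-odds PSSM scoring against shuffled
# controls.

#' Position-specific scoring matrix
#'
#' @param mat numeric 4 x W probability matrix with rownames A, C, G, T;
#'   columns must sum to 1 (within 1e-6 before pseudo-count).
#' @param motif_id motif name.
#' @param pseudo pseudo-count mixed in column-wise so every probability
#'   is strictly positive.
#' @return a `pssm` object.
#' @export
pssm <- function(mat, motif_id = "motif", pseudo = 1e-4) {
  if (!is.matrix(mat) || nrow(mat) != 4) stop("PSSM must be a 4 x W matrix")
  rownames(mat) <- c("A", "C", "G", "T")
  if (any(abs(colSums(mat) - 1) > 1e-6)) stop("PSSM columns must sum to 1")
  if (any(mat < 0)) stop("PSSM probabilities must be >= 0")
  mat <- sweep(mat + pseudo, 2, colSums(mat + pseudo), `/`)
  structure(list(motif_id = motif_id, mat = mat, pseudo = pseudo),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("pssm '%s', width %d\n", x$motif_id, ncol(x$mat)))
  invisible(x)
}

#' Read PSSMs from a minimal MEME-format motif file
#'
#' Parses `MOTIF <name>` records with their `letter-probability matrix`
#' blocks (alphabet ACGT).
#'
#' @param path MEME motif file.
#' @param pseudo pseudo-count applied to each matrix (see [pssm()]).
#' @return named list of `pssm` objects.
#' @export
read_meme <- function(path, pseudo = 1e-4) {
  lines <- readLines(path)
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) stop("no MOTIF records in ", path)
  out <- list()
  for (s in starts) {
    name <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    hdr <- grep("^letter-probability matrix", lines[seq(s, length(lines))])[1]
    hdr <- s + hdr - 1
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    mat <- t(vapply(rows, function(r) as.numeric(strsplit(trimws(r), "\\s+")[[1]]),
                    numeric(4), USE.NAMES = FALSE))
    out[[name]] <- pssm(t(mat), motif_id = name, pseudo = pseudo)
  }
  out
}

#' Write PSSMs in minimal MEME format
#' @param pssms list of [pssm()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pssms, path) {
  con <- file(path, "wt"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", ""), con)
  for (p in pssms) {
    writeLines(sprintf("MOTIF %s", p$motif_id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d", ncol(p$mat)), con)
    utils::write.table(format(t(p$mat), digits = 6), con, quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    writeLines("", con)
  }
  invisible(path)
}

#' Extract promoter windows around TSSs
#'
#' The window is `[TSS - flank, TSS + flank]` inclusive of the TSS
#' (`2*flank + 1` bases); minus-strand windows are reverse-complemented.
#' Windows running off a contig end are truncated and flagged. Exact
#' duplicate sequences are removed, keeping the first by input order.
#'
#' @param genome a `Biostrings::DNAStringSet` or FASTA path.
#' @param tss data.frame in BED6 layout (`chrom`, `start`, `end`,
#'   `name`, `score`, `strand`; 0-based half-open) or a BED file path.
#'   The TSS is taken as the interval start for `+` entries and the
#'   interval end for `-` entries.
#' @param flank flank size in bp (default 1000).
#' @return data.frame: `gene_id`, `sequence`, `gc`, `chrom`, `start`,
#'   `end` (1-based inclusive), `strand`, `truncated`.
#' @export
extract_promoters <- function(genome, tss, flank = 1000) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (is.character(tss)) {
    tss <- utils::read.table(tss, sep = "\t", stringsAsFactors = FALSE,
                             col.names = c("chrom", "start", "end", "name",
                                           "score", "strand"))
  }
  names(genome) <- sub("\\s.*$", "", names(genome))
  recs <- lapply(seq_len(nrow(tss)), function(i) {
    chrom <- tss$chrom[i]
    if (!chrom %in% names(genome)) stop("TSS contig absent from FASTA: ", chrom)
    # BED half-open 0-based: plus-strand TSS = start + 1 (1-based),
    # minus-strand TSS = end
    pos <- if (tss$strand[i] == "-") tss$end[i] else tss$start[i] + 1L
    clen <- Biostrings::width(genome[chrom])
    lo <- max(1L, pos - flank); hi <- min(clen, pos + flank)
    seq <- as.character(Biostrings::subseq(genome[[chrom]], lo, hi))
    if (tss$strand[i] == "-") {
      seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    }
    data.frame(gene_id = tss$name[i], sequence = seq,
               gc = gc_content(seq), chrom = chrom, start = lo, end = hi,
               strand = tss$strand[i],
               truncated = (hi - lo + 1L) < (2L * flank + 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out <- out[!duplicated(out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' GC content of DNA sequences
#'
#' `(G + C) / (A + C + G + T)`, case-insensitive; N and other ambiguity
#' codes are excluded from numerator and denominator.
#'
#' @param sequence character vector of DNA sequences.
#' @return numeric fractions in `[0, 1]`.
#' @export
gc_content <- function(sequence) {
  vapply(toupper(sequence), function(s) {
    b <- strsplit(s, "")[[1]]
    gc <- sum(b %in% c("G", "C"))
    at <- sum(b %in% c("A", "T"))
    if (gc + at == 0) stop("sequence has no unambiguous bases")
    gc / (gc + at)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Wilcoxon rank-sum comparison of two samples
#'
#' Exact enumeration when `length(x) + length(y) <= 12` and there are no
#' ties; otherwise the normal approximation with midranks, tie-corrected
#' variance and continuity correction.
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"`, `"less"` (x tends smaller) or
#'   `"greater"`.
#' @return the p-value.
#' @export
ranksum_test <- function(x, y, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  no_ties <- !anyDuplicated(c(x, y))
  exact <- (length(x) + length(y) <= 12) && no_ties
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE)$p.value
  )
}

# integer-encode an upper-case DNA string: A=1 C=2 G=3 T=4, else NA
encode_dna <- function(seq) {
  match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
}

#' Average-odds motif score of one sequence
#'
#' Mean over all start positions on both strands of the product of
#' per-base odds `p_motif(base) / p_background(base)`; windows touching
#' ambiguous bases contribute odds 1. A motif identical to the
#' background therefore scores exactly 1.
#'
#' @param sequence DNA string (length >= motif width).
#' @param pssm a [pssm()] object.
#' @param background length-4 base frequencies (A, C, G, T); default
#'   uniform.
#' @return the average odds score (>= 0).
#' @export
avg_odds_score <- function(sequence, pssm, background = rep(0.25, 4)) {
  W <- ncol(pssm$mat)
  fwd <- encode_dna(sequence)
  if (length(fwd) < W) stop("sequence shorter than the motif")
  background <- background / sum(background)
  lod <- log(pssm$mat) - log(background)  # 4 x W
  strand_scores <- function(enc) {
    nwin <- length(enc) - W + 1L
    tot <- numeric(nwin)
    bad <- logical(nwin)
    for (w in seq_len(W)) {
      b <- enc[w:(w + nwin - 1L)]
      miss <- is.na(b)
      bad <- bad | miss
      contrib <- lod[cbind(ifelse(miss, 1L, b), w)]
      contrib[miss] <- 0
      tot <- tot + contrib
    }
    out <- exp(tot)
    out[bad] <- 1
    out
  }
  rev_enc <- rev(5L - fwd)  # reverse complement in integer coding
  mean(c(strand_scores(fwd), strand_scores(rev_enc)))
}

#' Shuffle a DNA sequence
#'
#' Mononucleotide shuffling permutes the letters; dinucleotide shuffling
#' draws a random Eulerian walk through the dinucleotide transition
#' graph, preserving dinucleotide counts (and hence the first-order
#' composition).
#'
#' @param sequence DNA string.
#' @param method `"mono"` or `"di"`.
#' @return the shuffled string.
#' @export
shuffle_sequence <- function(sequence, method = c("mono", "di")) {
  method <- match.arg(method)
  b <- strsplit(toupper(sequence), "")[[1]]
  if (method == "mono") return(paste(sample(b), collapse = ""))
  n <- length(b)
  if (n < 3) return(paste(sample(b), collapse = ""))
  # random Eulerian walk: shuffle each letter's outgoing-edge list, then
  # retry until the walk uses every transition (simple rejection loop)
  succ <- split(b[-1], b[-n])
  for (try in 1:200) {
    pool <- lapply(succ, sample)
    out <- character(n); out[1] <- b[1]
    idx <- stats::setNames(rep(1L, length(pool)), names(pool))
    ok <- TRUE
    for (i in 2:n) {
      cur <- out[i - 1]
      k <- idx[[cur]]
      if (is.null(pool[[cur]]) || k > length(pool[[cur]])) { ok <- FALSE; break }
      out[i] <- pool[[cur]][k]
      idx[[cur]] <- k + 1L
    }
    if (ok && all(idx[names(pool)] == vapply(pool, length, integer(1)) + 1L)) {
      return(paste(out, collapse = ""))
    }
  }
  paste(sample(b), collapse = "")  # fallback: mononucleotide
}

#' Motif enrichment against shuffled controls
#'
#' Controls are one seeded shuffle per positive sequence. All sequences
#' are scored by [avg_odds_score()] (background: 0-order frequencies
#' estimated from the positives unless given). For every threshold at an
#' observed score value a one-tailed Fisher exact test is run on the
#' 2 x 2 table (score >= threshold x positive/control); the reported p
#' is the smallest Fisher p times the number of thresholds (Bonferroni),
#' capped at 1.
#'
#' @param positives named character vector of >= 5 positive sequences.
#' @param pssm a [pssm()] object.
#' @param seed integer seed for the shuffles.
#' @param background optional length-4 base frequencies.
#' @param shuffle `"mono"` or `"di"`.
#' @return list: `p`, `n_thresholds`, `best_threshold`, `scores_pos`,
#'   `scores_ctrl`.
#' @export
motif_enrichment <- function(positives, pssm, seed = 1L, background = NULL,
                             shuffle = c("mono", "di")) {
  shuffle <- match.arg(shuffle)
  if (length(positives) < 5) stop("need at least 5 positive sequences")
  if (is.null(background)) {
    tab <- table(factor(unlist(strsplit(toupper(paste(positives, collapse = "")), "")),
                        levels = c("A", "C", "G", "T")))
    background <- as.numeric(tab) / sum(tab)
    background[background == 0] <- 1e-6
  }
  controls <- with_seed(seed, vapply(positives, shuffle_sequence,
                                     character(1), method = shuffle))
  sp <- vapply(positives, avg_odds_score, numeric(1), pssm = pssm,
               background = background, USE.NAMES = FALSE)
  sc <- vapply(controls, avg_odds_score, numeric(1), pssm = pssm,
               background = background, USE.NAMES = FALSE)
  thr <- sort(unique(c(sp, sc)))
  if (length(thr) < 2) {
    return(list(p = 1, n_thresholds = 0L, best_threshold = NA_real_,
                scores_pos = sp, scores_ctrl = sc))
  }
  thr <- thr[-1]  # lowest threshold puts everything "above": uninformative
  pvals <- vapply(thr, function(t0) {
    a <- sum(sp >= t0); b <- sum(sp < t0)
    c0 <- sum(sc >= t0); d0 <- sum(sc < t0)
    stats::fisher.test(matrix(c(a, b, c0, d0), 2), alternative = "greater")$p.value
  }, numeric(1))
  k <- which.min(pvals)
  list(p = min(1, pvals[k] * length(thr)), n_thresholds = length(thr),
       best_threshold = thr[k], scores_pos = sp, scores_ctrl = sc)
}

#' Enrichment of a motif set with BH adjustment
#'
#' @param positives named character vector of positive sequences.
#' @param pssms list of [pssm()] objects.
#' @param seed integer seed (one shuffle set per motif, offset by index).
#' @param ... passed to [motif_enrichment()].
#' @return data.frame `motif_id`, `p`, `adj_p`, `n_pos`, `n_ctrl`.
#' @export
motif_enrichment_set <- function(positives, pssms, seed = 1L, ...) {
  ps <- vapply(seq_along(pssms), function(i) {
    motif_enrichment(positives, pssms[[i]], seed = seed + i - 1L, ...)$p
  }, numeric(1))
  data.frame(
    motif_id = vapply(pssms, `[[`, character(1), "motif_id"),
    p = ps, adj_p = bh_adjust(ps),
    n_pos = length(positives), n_ctrl = length(positives),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write sequences as FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
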