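write_toy_genome <- function() {
  # deterministic 12 kb contig plus a short one for truncation tests
  set.seed(20)
  chr1 <- paste(sample(c("A", "C", "G", "T"), 12000, replace = TRUE),
                collapse = "")
  chrS <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                collapse = "")
  fa <- tempfile(fileext = ".fa")
  write_fasta(c(chr1 = chr1, chrS = chrS), fa)
  list(path = fa, chr1 = chr1, chrS = chrS)
}

test_that("promoter extraction follows the inclusive window convention", {
  g <- write_toy_genome()
  # BED 0-based half-open; plus-strand TSS at 1-based position 5000
  tss <- data.frame(chrom = "chr1", start = 4999, end = 5001,
                    name = "geneA", score = 0, strand = "+")
  rec <- extract_promoters(g$path, tss, flank = 1000)
  expect_equal(nchar(rec$sequence), 2001)
  expect_equal(rec$sequence, substr(g$chr1, 4000, 6000))
  expect_false(rec$truncated)

  # minus strand: reverse complement of the window around TSS = end
  tss_m <- data.frame(chrom = "chr1", start = 4999, end = 5001,
                      name = "geneB", score = 0, strand = "-")
  rec_m <- extract_promoters(g$path, tss_m, flank = 1000)
  fwd <- substr(g$chr1, 4001, 6001)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  expect_equal(rec_m$sequence, rc)

  # truncation at contig ends is flagged
  tss_t <- data.frame(chrom = "chrS", start = 49, end = 51, name = "geneC",
                      score = 0, strand = "+")
  rec_t <- extract_promoters(g$path, tss_t, flank = 1000)
  expect_true(rec_t$truncated)
  expect_equal(nchar(rec_t$sequence), 300)

  # exact duplicate windows keep the first record only
  tss_d <- rbind(tss, transform(tss, name = "geneA2"))
  rec_d <- extract_promoters(g$path, tss_d, flank = 1000)
  expect_equal(nrow(rec_d), 1)
  expect_equal(rec_d$gene_id, "geneA")

  expect_error(extract_promoters(g$path,
                                 transform(tss, chrom = "chrX"), 1000),
               "absent")
})

test_that("gc_content counts unambiguous bases only", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATAT"), 0.0)
  expect_equal(gc_content("ACGTN"), 0.5)
  expect_equal(gc_content("acgt"), 0.5)
  expect_error(gc_content("NNN"), "unambiguous")
  # invariances: reverse complement preserves GC
  s <- "ACGGTTACGN"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(gc_content(s), gc_content(rc))
})

test_that("rank-sum test: exact small-sample case and approximation accuracy", {
  expect_equal(ranksum_test(c(1, 2, 3), c(4, 5, 6), "less"), 1 / 20)
  expect_equal(ranksum_test(c(1, 2, 3), c(1, 2, 3)), 1)
  # exact vs normal approximation within 0.02 on n = 8 + 8 draws
  set.seed(22)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8, 0.3)
    p_approx <- ranksum_test(x, y)  # 16 > 12 samples: approximation
    p_exact <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    expect_lt(abs(p_approx - p_exact), 0.02)
  }
  expect_error(ranksum_test(numeric(0), 1), "non-empty")
})

test_that("average-odds scoring: background identity, window count, strand symmetry", {
  bg_mat <- matrix(0.25, 4, 5)
  p_bg <- pssm(bg_mat, "flat")
  set.seed(23)
  seqs <- vapply(1:10, function(i) {
    paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  }, character(1))
  for (s in seqs) {
    expect_equal(avg_odds_score(s, p_bg), 1, tolerance = 1e-12)
  }
  # strand symmetry: reverse complement leaves the score unchanged
  motif <- pssm(matrix(c(0.91, 0.03, 0.03, 0.03), 4, 8), "polyA")
  for (s in seqs[1:5]) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(avg_odds_score(s, motif), avg_odds_score(rc, motif),
                 tolerance = 1e-9)
  }
  # planted motif scores above the same sequence shuffled
  host <- paste(rep("C", 50), collapse = "")
  planted <- paste0(substr(host, 1, 20), "AAAAAAAA", substr(host, 29, 50))
  set.seed(24)
  shuf <- shuffle_sequence(planted)
  expect_gt(avg_odds_score(planted, motif), avg_odds_score(shuf, motif))
  expect_error(avg_odds_score("ACG", motif), "shorter")
})

test_that("MEME round-trip preserves matrices", {
  m1 <- pssm(matrix(c(0.7, 0.1, 0.1, 0.1,
                      0.1, 0.7, 0.1, 0.1,
                      0.25, 0.25, 0.25, 0.25), 4), "toy1")
  m2 <- pssm(matrix(0.25, 4, 6), "toy2")
  path <- tempfile(fileext = ".meme")
  write_meme(list(m1, m2), path)
  back <- read_meme(path)
  expect_equal(names(back), c("toy1", "toy2"))
  expect_equal(back$toy1$mat, m1$mat, tolerance = 1e-3)
  expect_equal(ncol(back$toy2$mat), 6)
})

test_that("dinucleotide shuffling preserves dinucleotide counts", {
  set.seed(25)
  s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE,
                    prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
  dinuc <- function(x) {
    b <- strsplit(x, "")[[1]]
    table(paste0(b[-length(b)], b[-1]))
  }
  sh <- shuffle_sequence(s, method = "di")
  expect_equal(sort(names(dinuc(sh))), sort(names(dinuc(s))))
  d1 <- dinuc(s); d2 <- dinuc(sh)
  expect_equal(as.integer(d2[names(d1)]), as.integer(d1))
})

test_that("motif enrichment detects planted motifs and the Fisher tail is exact", {
  motif <- pssm(local({
    core <- c("T", "G", "A", "C", "G", "T", "C", "A")
    m <- matrix(0.03, 4, 8, dimnames = list(c("A", "C", "G", "T"), NULL))
    for (j in seq_along(core)) m[core[j], j] <- 0.91
    m
  }), "planted")
  prom <- gen_promoters(30, 0, length = 120, gc_pos = 0.5, gc_neg = 0.5,
                        motif = motif, plant_rate = 1, seed = 26)
  res <- motif_enrichment(prom$positives, motif, seed = 27)
  expect_lt(res$p, 0.01)

  # no planted motif: no significant enrichment at this single seed
  prom0 <- gen_promoters(30, 0, length = 120, gc_pos = 0.5, gc_neg = 0.5,
                         motif = motif, plant_rate = 0, seed = 28)
  res0 <- motif_enrichment(prom0$positives, motif, seed = 29)
  expect_gt(res0$p, 0.05)

  # the one-tailed Fisher building block equals the closed-form
  # hypergeometric tail
  p_fisher <- stats::fisher.test(matrix(c(10, 0, 2, 8), 2),
                                 alternative = "greater")$p.value
  expect_equal(p_fisher, hyper_tail_oracle(10, 0, 2, 8), tolerance = 1e-12)

  # motif-set wrapper returns BH-adjusted values
  st <- motif_enrichment_set(prom$positives, list(motif), seed = 27)
  expect_equal(st$adj_p, st$p)
  expect_error(motif_enrichment(prom$positives[1:3], motif), "at least 5")
})
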