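# splicerhythm

Detection and characterisation of circadian (24-h) and ultradian
(12-h) rhythms in expression time courses, at both gene and transcript
level, with a focus on **rhythmic alternative splicing**: phase-shifted
isoform pairs in RNA-seq data and rhythmic exon-inclusion signatures in
probe-level array data.

## Who this is for

Chronobiologists and transcriptomics analysts with a densely sampled
time course (e.g. every 2 h over 24–48 h, or every 3 h over 30 h) who
want to go beyond gene-level rhythm calling. Summing reads to gene
level can *mask* rhythmicity: two isoforms of one gene cycling in
antiphase add up to a flat profile. Conversely a gene can appear
rhythmic with no rhythmic isoform. This package detects rhythms at both
levels, tests isoform pairs for differential rhythmicity, and scans
probe-level arrays for splicing events that themselves cycle.

## What is inside

| Stage | Method |
|---|---|
| Normalisation | TMM scale factors (edgeR), log2 CPM, mean-CPM ≥ 0.5 filter with renormalisation |
| Rhythm test | rank-based umbrella test: circular Mack–Wolfe statistics over candidate peak phases, combined by log-mean-exp and calibrated against a cached permutation null |
| Characterisation | cosinor fit `y = m + a·cos(2πt/T) + b·sin(2πt/T)` (Huber-robust), peak phase `(T/2π)·atan2(b,a) mod T`, relative amplitude `√(a²+b²)/|m|` ≥ 0.1 filter before BH FDR |
| Isoform pairs | nested harmonic-model F-test (shared rhythm + free mesors vs free rhythm), Huber-robust with simulation-calibrated reference; phase-shifted call: q < 0.05, amplitude ratio < 2, phase shift ≥ T/6 (24 h) or 2–3 h (12 h) |
| Array splicing scores | quantile normalisation, per-gene median polish, CUSUM-style max over probe runs of `|Σz|/√len` on MAD-standardised residuals, rhythm scan at q < 0.1 |
| Phase statistics | circular mean/median/dispersion, circular k-means with seeded restarts |
| Promoters & motifs | TSS ± flank extraction (strand-aware, deduplicated), GC content, Wilcoxon rank-sum, average-odds PSSM scoring on both strands, Fisher exact enrichment vs per-sequence shuffled controls |
| Synthetic data | negative-binomial transcript counts with multiplicative planted rhythms, probe-level arrays with planted exon events, promoter sets with planted motifs — all with ground-truth tables and bit-reproducible seeds |

Three dataset profiles (`pipeline_profile()`) encode the usual
threshold regimes: `array48h2h` (q < 0.05; splicing scan q < 0.1),
`rnaseq24h2h` (p < 0.005; pairs built at p < 0.005 / p < 0.05),
`rnaseq30h3h` (p < 0.05 throughout, 12-h minimum shift 3 h).

## Worked example

```r
library(splicerhythm)

d <- tempfile(); make_fixture("masking_demo", d)   # seeded demo scene
tx  <- read_timed_matrix(file.path(d, "transcript_counts.tsv"))
t2g <- read.table(file.path(d, "tx2gene.tsv"), header = TRUE)

tx
#> timed_matrix: 7 features x 24 samples [counts], t = 0..46 h

res <- run_rnaseq_pipeline(tx, t2g, pipeline_profile("array48h2h"))
str(res$stages)
#> List of 6
#>  $ input_tx           : int 7
#>  $ expressed_tx       : int 7
#>  $ rhythmic_tx        : int 3
#>  $ rhythmic_gene      : int 1
#>  $ candidate_pairs    : int 1
#>  $ phase_shifted_pairs: int 1

subset(res$calls, phase_shifted)
#>   gene_id     tx_a     tx_b period_h       dodr_p       dodr_q  phase_a
#> 1   g0001 g0001.t1 g0001.t2       24 4.693772e-11 4.693772e-11 5.852049
#>    phase_b phase_diff_h amp_ratio phase_shifted
#> 1 17.12853     11.27648  1.156599          TRUE
```

The demo scene plants one gene with two equal-amplitude isoforms
peaking ~12 h apart. The pipeline finds 3 rhythmic transcripts but only
1 rhythmic *gene*: the antiphasic pair cancels in the gene-level sum
(`res$level_comparison` shows one gene rhythmic at transcript level
only), and the pair is called phase-shifted with a fitted phase
difference of ~11.3 h and amplitude ratio ~1.16.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/splicerhythm.R simulate --scene masking_demo --out-dir demo
Rscript inst/cli/splicerhythm.R run --counts demo/transcript_counts.tsv \
    --tx2gene demo/tx2gene.tsv --profile array48h2h --out-dir demo/out
# rhythmic tx: 3 | rhythmic genes: 1 | pairs: 1 | phase-shifted: 1
```

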