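# dcde — integrated differential co-expression / differential expression analysis

`dcde` is for transcriptomics analysts comparing two sample classes (e.g.
tumour vs normal) who want more than a differential-expression list: it
finds genes whose co-expression neighbourhood is *rewired* between the
classes **and** whose own level shifts, and it quantifies — in bits —
whether combining the two criteria buys real functional signal over either
one alone.

## The method

For a genes × samples matrix with case/control labels:

1. **DE** per gene: the unpooled two-sample statistic
   `t_i = (x̄_D − x̄_N) / sqrt(s_D²/n_D + s_N²/n_N)`; `|t_i|` is the DE
   magnitude.
2. **DC** per gene pair: per-class Pearson correlations compared on the
   Fisher-z scale,
   `Z_ij = |z^N_ij − z^D_ij| / sqrt(1/(n_N−3) + 1/(n_D−3))`, an approximate
   absolute z-score for "the correlation changed".
3. **Threshold selection** per focal gene i: every observed point
   `(Z_ij, |t_j|)` is tried as a threshold pair; the pair maximizing the
   Pearson chi-square of the induced 2×2 high/low contingency table is the
   gene's optimal `(z*, t*)`. The search is O(m log m) (Fenwick-tree
   dominance counting) and provably identical to the exhaustive scan.
4. **Significance**: the maximum chi-square is referred to the df = 1 upper
   tail, Bonferroni-corrected for the m candidate tests, then BH-corrected
   across genes; the adjusted residual of the high-DC/high-DE cell signs
   the association.
5. **Functional information**: each significant positive partition is
   tested against gene sets (two-tailed Fisher exact, Bonferroni ×k, BH
   across partitions); `FI = −log2(p_adj)` bits, and the minimum FI gain
   `Δ* = min(FI_HDC_HDE − FI_HDE, FI_HDC_HDE − FI_HDC)` measures what the
   *combination* adds. Gene sets are ranked by mean Δ*.

The package also ships the matching independence-null simulation of the
maximum chi-square (false-positive control of the Bonferroni+BH cascade), a
noncentral-t minimum-sample-size utility, and a synthetic-data generator
with a planted co-expressed, differentially expressed block for end-to-end
testing.

## Worked example

```r
library(dcde)

syn <- synth_dataset(m = 150, n_case = 50, n_control = 50, block_size = 20,
                     rho = 0.8, delta = 1.5, n_decoy_sets = 5, seed = 3)
fit <- dcde(syn$dataset, syn$gene_sets)
fit
#> Integrated DC/DE analysis (chi-square maximization)
#>   150 genes, 50 case / 50 control samples
#>   thresholds selected for 150 genes (0 without valid candidates)
#>   significant DC-DE dependency after Bonferroni+BH at alpha = 0.05: 29 (29 positive)
#>   enrichment: 29 partitions scored against 6 gene sets
#>   top set by mean minimum FI gain: planted_block (4.0 bits over 29 partitions)
```

All 20 planted genes are among the 29 significant focal genes, and the
planted set tops the ranking with a mean minimum FI gain of 4.0 bits —
i.e. on average its partitions are 2^4 ≈ 16 times more significantly
associated under the combined high-DC/high-DE criterion than under the
weaker of the two single criteria. Per-gene detail lives in
`fit$results` (thresholds, max chi-square, cascade p-values, partition
sizes, residual direction):

```r
head(fit$results[order(-fit$results$max_chi2),
                 c("gene_id", "abs_t", "z_star", "t_star", "max_chi2", "p_bh")], 3)
#>   gene_id abs_t z_star t_star max_chi2     p_bh
#>     g0008  8.90   2.06   1.85     82.3 2.60e-15
#>     g0017  8.31   2.50   1.80     70.9 4.31e-13
#>     g0007  8.37   2.48   1.77     67.9 1.26e-12
```

The null simulation shows why the cascade is needed — under independence
*every* per-gene maximum beats the naive 3.841 cutoff, yet almost nothing
survives the corrections:

```r
simulate_null(m = 1000, replicates = 100, seed = 1, min_expected = 3)
#> Independence-null simulation of the maximum chi-square
#>   m = 1000 points/replicate, 100 replicates (t_df = 100, min_expected = 3)
#>   mean max chi2 = 9.35, 95th percentile = 15.44
#>   significant at alpha = 0.05: raw 100, after Bonferroni 1, after BH 0

min_sample_size_t(d = 0.5, alpha = 0.05, power = 0.8)
#> [1] 128
```

Real data enter through TSV files (`read_expression(matrix, labels)`) and
GMT gene sets (`read_gmt`); a thin command-line wrapper with `run`,
`simulate`, `generate` and `power` subcommands is installed at
`inst/cli/dcde-cli.R`. See the methods vignette
(`vignettes/dcde-methods.Rmd`) for the statistical design, parameter
defaults and limitations.

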