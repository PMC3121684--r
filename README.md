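# agscan — aggregation propensity versus protein turnover

Protein aggregation is nucleated by short sequence stretches that assemble
into intermolecular beta-sheets. Evolution counteracts this by placing
*gatekeeper* residues (P, R, K, E, D) at the flanks of aggregation-prone
regions — but is that selective pressure uniform across the proteome, or
does it depend on how long a protein lives? A protein with fast proteasomal
turnover spends little time in aggregation-competent states and may tolerate
a higher intrinsic aggregation propensity.

`agscan` is an R package for proteome-scale analyses of this question. It is
aimed at structural bioinformaticians who have per-residue beta-aggregation
propensity profiles (from any predictor, 0–100 scale) and experimental
turnover measurements (PSI, a 1–7 protein stability index, higher = slower
turnover), and want the full comparative pipeline:

* **Segment calling** — an aggregating segment is a maximal run of ≥ 5
  consecutive residues each scoring strictly above 5. Four metrics per
  protein: length-normalized total score, segment count, segment lengths,
  per-segment mean propensities.
* **Gatekeeper flanks** — the 5 positions on each side of every segment
  (truncated at termini, N/C pooled); gatekeeper frequency is the fraction
  of flank positions carrying P, R, K, E or D.
* **Lifetime comparison** — short-living (PSI ≤ 2) versus long-living
  (PSI ≥ 5) groups, Mann–Whitney and Kolmogorov–Smirnov tests per metric,
  with a length-restricted control (≤ 300 residues) and expression-stratified
  means to exclude the obvious confounds.
* **Chaperone-binding enrichment** — over four PSI categories
  (< 2, [2, 3), [3, 4), ≥ 4), the statistic
  `e(c) = PSI_N(c)/PSI_T(c) − SUM_N/SUM_T` for subset N within total set T,
  plus a deposition-disease tally per category.
* **Stability correlation** — per-segment thermodynamic stabilities
  (kcal/mol, inputs) correlated with segment propensity, raw (`r_raw`) and
  on per-propensity-bin means (`r_bin`), per lifetime group.
* **Synthetic proteomes** — a generator that plants configurable group
  effects (segment strength/length, gatekeeper density, chaperone labels,
  expression, stability) with a truth log, so every stage is testable
  without external data.

Membrane (`KW-472`) and extracellular-matrix (`KW-0272`) proteins are
filtered out before analysis. All coordinates are 1-based inclusive, in
memory and on disk. See the vignette
(`vignettes/aggregation-turnover.Rmd`) for the methods in full.

## Worked example

```r
library(agscan)

cfg      <- synthetic_config(n_short = 80, n_long = 120)
proteome <- generate_proteome(cfg, seed = 7)
scan     <- summarize_proteome(proteome$records, proteome$profiles)
scan
#> Aggregation scan: 200 proteins, 621 aggregating segments
#>   mean normalized score: 3.135
#>   mean flank gatekeeper frequency: 0.310

psi <- setNames(proteome$records$psi, proteome$records$protein_id)
compare_all_metrics(scan, psi)[, c("metric", "n_short", "n_long",
                                   "mw_p", "ks_p", "direction")]
#>                 metric n_short n_long     mw_p     ks_p direction
#> 1     normalized_score      80    120 3.59e-05 7.89e-05         1
#> 2           n_segments      80    120 1.87e-02 1.21e-01        -1
#> 3 gatekeeper_frequency      71    119 2.11e-11 5.47e-10        -1
#> 4       segment_length     219    402 8.13e-09 1.96e-06         1
#> 5   segment_propensity     219    402 1.40e-65 0.00e+00         1
```

Reading the table: the short-living group has a higher aggregation load
(`direction = 1` with p = 3.6e-05 for the normalized score), driven by
longer and stronger segments rather than by more of them, and its flanks
carry fewer gatekeepers (`direction = -1` for `gatekeeper_frequency`) —
exactly the effect structure this configuration plants. The per-segment
metrics use the segment as the unit of observation (219 + 402 segments),
the others the protein (80 + 120).

```r
res <- bin_and_correlate(
  join_segment_stability(scan, proteome$stability, psi))
res$correlations
#>   group   n r_raw r_bin
#> 1 short 219  0.25  0.85
#> 2  long 402  0.22  0.88
```

Bin averaging removes independent per-segment noise, so the binned
correlation between segment propensity and (negated) stability rises well
above the raw one: strongly aggregating segments sit in the most stable
parts of the native fold, equally in both lifetime groups.

For file-based workflows, `write_fixture_set()` / `run_full_analysis()`
read and write FASTA plus TSV tables and emit a complete report directory
(summary, segments, flagged comparison table, enrichment, disease tally,
expression strata, stability bins, JSON manifest); the same operations are
available from the shell via `Rscript inst/scripts/agscan.R <subcommand>`.

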