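---
title: "Relating aggregation propensity to protein turnover with agscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relating aggregation propensity to protein turnover with agscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Short-stretch protein aggregation is nucleated by contiguous sequence
segments that can assemble into intermolecular beta-sheets. Because such
segments overlap heavily with the hydrophobic cores that globular folds
require, few proteins are free of them; evolution instead mitigates the risk
by placing *gatekeeper* residues — proline (a beta-breaker), and the charged
residues arginine, lysine, aspartate and glutamate — at the flanks of
aggregation-prone regions. agscan asks whether this selective pressure is
uniform across the proteome or depends on a protein's biological lifetime:
a protein that is degraded quickly spends little time in partially folded,
aggregation-competent states, so fast-turnover proteins may tolerate a
higher intrinsic aggregation propensity.

The package implements the full comparative pipeline: segment calling from
per-residue propensity profiles, gatekeeper flank statistics, turnover
stratification, two-group distribution tests with confound controls,
chaperone-binding enrichment, and binned propensity-versus-stability
correlation — plus a synthetic proteome generator that makes every stage
testable end to end.

## Inputs and conventions

* **Per-residue profiles** are vectors of beta-aggregation propensities on a
  0–100 scale, one value per residue, typically parsed from an external
  predictor's tab-delimited output (`read_profile_file()`). The predictor
  itself is out of scope; `surrogate_profile()` provides a clearly labelled
  deterministic stand-in (see below).
* **PSI** (protein stability index) is an experimental turnover measure on a
  1–7 scale, higher meaning slower turnover. Records without PSI simply drop
  out of lifetime analyses; PSI is never imputed.
* **Coordinates** are 1-based and inclusive everywhere — in memory and in
  every file. This is the native R and Bioconductor convention; using it
  internally as well as externally removes an entire class of off-by-one
  conversions.
* Sequences are validated against the 20 standard residues by default;
  lenient mode maps the ambiguity codes B/Z/X/U/O to the placeholder `X`,
  which is scored 0 by the surrogate and never counted as a gatekeeper.
* Trans-membrane and extracellular-matrix proteins (keywords `KW-472`,
  `KW-0272`) are removed before analysis: trans-membrane stretches are
  hydrophobic by necessity rather than under anti-aggregation selection, and
  extracellular proteins are degraded by lysosomes, not the proteasome. The
  filter is purely keyword-presence based; proteins carrying both a membrane
  keyword and cytosolic isoforms are removed like any other flagged record.

## Segment calling and gatekeeper flanks

An *aggregating segment* is a maximal run of at least `min_len = 5`
consecutive residues whose scores each **strictly** exceed `threshold = 5`.
The comparison is strict: a residue scoring exactly 5.0 terminates a run,
and the residues bordering a segment (when they exist) are at or below the
threshold. `call_segments()` returns segments in ascending order; they are
therefore disjoint and separated by at least one sub-threshold residue.

The *gatekeeping flanks* are the `flank_size = 5` positions on each side of
a segment, truncated (never padded) at the sequence termini, with N- and
C-side positions pooled. The per-protein gatekeeper frequency is the
fraction of flank positions carrying P, R, K, E or D, pooled over all
segments of the protein with multiplicity one per segment-flank membership:
when two segments sit fewer than ten residues apart, a position inside both
flanks counts once for each. This preserves per-segment flank semantics;
frequency denominators always use actual (possibly truncated) flank sizes,
so no phantom positions are invented.

Four per-protein metrics summarize a profile: the length-normalized score
(total score / protein length), the number of segments, the per-segment
lengths, and the per-segment propensities. The per-segment propensity is
the **mean** per-residue score over the segment: the mean is
length-independent, which matters because segment length is reported as its
own metric (the sum is also returned as `sum_score`).

## Group comparisons and controls

PSI stratifies proteins into short-living (PSI ≤ 2) and long-living
(PSI ≥ 5) groups; intermediate values are excluded. For per-protein metrics
the unit of observation is the protein; for segment length and segment
propensity it is the segment, matching how those distributions are defined.

Both a Mann–Whitney and a Kolmogorov–Smirnov test are applied, two-sided
throughout; the direction annotation (`++`/`+`/`0`/`-`/`--` at p < 0.001
and p < 0.01) is derived from the sign of the median difference, short
minus long. Two-sided testing with a separate direction flag is the
conservative choice. No multiple-testing correction is applied across the
five metrics; p-values are reported raw, per metric, and should be read as
such. The Mann–Whitney implementation uses the exact distribution for small
tie-free samples and the normal approximation with midrank tie correction
and continuity correction otherwise; the Kolmogorov–Smirnov p-value is
asymptotic.

Two confound controls accompany the main comparison:

* **Length restriction** (`max_len = 300` residues): long-living proteins
  are on average longer, and longer proteins tend to have weaker
  aggregating regions, so the comparison is repeated after dropping
  proteins longer than 300 residues. `length_binned_profile()` (default
  100-residue bins) shows the group gap as a function of length directly.
* **Expression stratification**: since expression level is tuned against
  solubility, proteins are binned by normalized log-scale expression
  (default integer-width bins spanning the observed range — the binning is
  configurable because no canonical choice exists) and group means are
  compared within bins. A genuine lifetime effect persists inside every
  populated bin; a pure expression confound does not.

## Enrichment and the disease tally

For chaperone binding, PSI is split into four categories: short (PSI < 2),
medium (2 ≤ PSI < 3), long (3 ≤ PSI < 4), extra-long (PSI ≥ 4). Note the
deliberate boundary asymmetry with the two-group rule (PSI ≤ 2 for
"short"): both rules are implemented exactly as defined and never unified,
since each belongs to a different analysis. The enrichment of a subset N
inside a total set T in category c is

    e(c) = PSI_N(c) / PSI_T(c) − SUM_N / SUM_T,

with `PSI_x(c)` the category count of set x and `SUM_x` its size. The
counts obey the exact identity `Σ_c PSI_T(c)·e(c) = 0` whenever N ⊆ T, and
the complement satisfies `e_complement(c) = −e(c)`; both are enforced by
tests. Categories with `PSI_T(c) = 0` are reported as undefined rather than
dropped, so tables keep a fixed shape. No significance test is attached to
enrichment values. `disease_category_tally()` counts deposition-disease
proteins per category and reports the combined short+medium count.

## Stability correlation

Per-segment thermodynamic stabilities (free-energy contributions in
kcal/mol, **lower = more stable**) are inputs, matched to called segments
by exact coordinates. Within each lifetime group, `bin_and_correlate()`
computes the product-moment correlation between segment propensity and
stability on the raw pairs (`r_raw`) and on per-bin means (`r_bin`) over
propensity bins — by default 10 equal-width bins over the pooled observed
propensity range, shared by both groups so the bins are comparable. The
correlation is computed against negated stability values, so a positive
correlation reads "more aggregation-prone ⇒ more stable in the native
fold"; bin means are reported in the original units. Bin averaging removes
independent within-bin noise, so `r_bin` exceeds `r_raw` whenever the
underlying trend is monotone with additive noise. With one segment per bin
the two coincide exactly. No p-values are attached to these correlations.
With fewer than two populated bins, `r_bin` is reported as undefined; with
zero variance in either variable, correlations are `NA` rather than a
warning.

## The surrogate scorer

`surrogate_profile()` is a deliberately simple deterministic scorer so the
pipeline runs without an external predictor: a centered width-5 sliding
window average of a fixed residue table combining hydrophobicity with
beta-sheet preference, affine-rescaled so the table maximum maps to 100 and
non-positive window means map to 0. Gatekeepers carry strongly negative
table entries, so a single proline or charged residue suppresses every
window containing it. The surrogate is translation-symmetric and
reversal-symmetric by construction. It is **not** a statistical-mechanics
predictor — it has no notion of segment cooperativity or conformational
states — and biological conclusions should rest on real predictor output.

## What the synthetic generator emulates — and what it does not

`synthetic_config()` defaults encode the study conditions the analysis
assumes: 191 short-living and 420 long-living proteins (the post-filter
group sizes of the reference turnover dataset), log-normal protein lengths
targeting group means of about 263 and 357 residues (`sdlog = 0.5`, a
realistic proteome-scale spread), about 3 planted segments per protein in
both groups (the number of segments is deliberately *not* different between
groups), segment lengths of `5 + Geometric(p)` with `p = 0.25` (short) vs
`0.4` (long), planted per-residue score levels of 40 vs 30 (each segment
draws its level from a Normal with sd 5, truncated to [10, 100]), flank
gatekeeper probabilities of 0.25 vs 0.35, PSI uniform on [1, 2] and [5, 7],
chaperone-binding probability increasing over the four PSI categories
(0.10/0.18/0.25/0.30), deposition-disease probabilities chosen so the
expected tally is 15 short-group and 1 long-group protein, a 0.5-unit
log-expression shift between groups, and per-segment stability
`−0.05·score + Normal(0, 1)` kcal/mol. Where the underlying study reports
no value (score levels, flank probabilities, expression parameters, the
stability slope and noise), the defaults were chosen once as plausible
field-scale magnitudes that reproduce the qualitative patterns — they are
study conditions, not tuning knobs.

Generated sequences are background draws from human-like residue
frequencies; planted segment bodies use a hydrophobic alphabet and their
flanks are populated gatekeeper-or-not per position. Planted segments are
separated by at least `2·flank_size + 1` background residues so flanks
never overlap a neighbouring segment body, keeping the planted flank
probability recoverable without dilution; segments that cannot be placed in
a sampled protein are dropped, and the truth log records exactly what was
planted. Background scores are 0 by default (clean, boundary-exact
recovery); `background_noise = TRUE` adds sub-threshold jitter in [0, 5) to
exercise threshold strictness. A single integer seed drives one pseudo-random
stream for all draws, and the caller's RNG state is restored afterwards, so
fixtures are exactly reproducible. `null_effect = TRUE` sets every per-group
parameter to the long-group value, making the groups exchangeable — the
null-calibration configuration.

The generator does *not* emulate: evolutionary sequence structure or
homology, realistic predictor score shapes (planted segments have flat
score plateaus), microarray noise models, or any dependence between
expression and aggregation beyond what a configuration explicitly plants.
Passing tests on synthetic proteomes therefore demonstrates that the
pipeline recovers planted statistical structure at realistic sizes — not
that any biological claim holds on real data.

## Test and verification sizes

The test suite verifies the segment caller against a brute-force
window-enumeration oracle on 1,000 random profiles (lengths 1–200, score
atoms at 0 and at the threshold), the Mann–Whitney p-value against
exhaustive rank-set enumeration for all group sizes up to 9, the enrichment
zero-sum identity on 1,000 fuzzed subset instances, type-I error
calibration over 1,000 null proteomes of 200 proteins per group (rejection
fraction at p < 0.05 required to lie in [0.02, 0.09]), planted-effect
recovery over 100 seeds at 200 proteins per group, and the
`r_bin > r_raw` pattern over 100 seeds at 500 segments per group. These
sizes give stable pass/fail behaviour at desk scale and were fixed before
being run routinely.

## Known limitations

* Profiles are inputs; the package deliberately contains no aggregation
  predictor beyond the labelled surrogate, no force-field stability
  calculation, and no expression preprocessing.
* The asymptotic Kolmogorov–Smirnov p-value is approximate in the presence
  of heavy ties (e.g. segment counts); the Mann–Whitney test, which handles
  ties by midranks, is the primary test for such metrics.
* Enrichment values come without significance tests, mirroring how such
  tables are usually reported; treat them descriptively.
* The two-group and four-category PSI boundary conventions differ by design
  and must not be mixed across analyses.
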