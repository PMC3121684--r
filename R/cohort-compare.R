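# Lifetime grouping by PSI and two-group distribution comparisons of the
# aggregation metrics, with length- and expression-stratified controls.

#' Assign two-group lifetime labels from PSI
#'
#' Proteins are split at the extremes of the turnover distribution:
#' short-living (PSI <= 2) versus long-living (PSI >= 5); intermediate
#' PSI values are excluded from two-group analyses.
#'
#' @param psi numeric PSI vector (values in `[1, 7]`, `NA` allowed).
#' @return Factor with levels `short`, `intermediate`, `long` (`NA` for
#'   missing PSI).
#' @export
assign_lifetime_group <- function(psi) {
  bad <- !is.na(psi) & (psi < 1 | psi > 7)
  if (any(bad)) stop("PSI outside [1, 7]")
  out <- rep(NA_character_, length(psi))
  out[!is.na(psi) & psi <= 2] <- "short"
  out[!is.na(psi) & psi >= 5] <- "long"
  out[!is.na(psi) & psi > 2 & psi < 5] <- "intermediate"
  factor(out, levels = c("short", "intermediate", "long"))
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum comparison of two samples. The exact null distribution is used
#' for small tie-free samples; otherwise the normal approximation with
#' midrank tie correction and continuity correction. The statistic is the
#' U count for `a` (number of pairs `(a_i, b_j)` with `a_i > b_j`, ties
#' counted half).
#'
#' @param a,b numeric samples (each non-empty).
#' @return `list(statistic = U, p.value = two-sided p)`.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  res <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE))
  list(statistic = unname(res$statistic), p.value = res$p.value)
}

#' Two-sided two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum distance between the two empirical CDFs; the p-value
#' uses the asymptotic distribution.
#'
#' @param a,b numeric samples (each non-empty).
#' @return `list(statistic = D, p.value = p)`.
#' @export
kolmogorov_smirnov <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  res <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(statistic = unname(res$statistic), p.value = res$p.value)
}

#' Aggregation metrics available for group comparison
#'
#' Per-protein metrics (`normalized_score`, `n_segments`,
#' `gatekeeper_frequency`) take the protein as the unit of observation;
#' per-segment metrics (`segment_length`, `segment_propensity`) take the
#' aggregating segment.
#' @export
COMPARISON_METRICS <- c("normalized_score", "n_segments",
                        "gatekeeper_frequency", "segment_length",
                        "segment_propensity")

# Extract the observation vectors for one metric, split short vs long.
metric_observations <- function(scan, psi, metric, max_len = NULL) {
  metric <- match.arg(metric, COMPARISON_METRICS)
  summary <- scan$summary
  summary$psi <- unname(psi[summary$protein_id])
  summary$group <- assign_lifetime_group(summary$psi)
  if (!is.null(max_len)) summary <- summary[summary$length <= max_len, , drop = FALSE]
  per_protein <- metric %in% c("normalized_score", "n_segments",
                               "gatekeeper_frequency")
  if (per_protein) {
    values <- summary[[metric]]
    group <- summary$group
  } else {
    segs <- scan$segments[scan$segments$protein_id %in% summary$protein_id, ,
                          drop = FALSE]
    values <- if (metric == "segment_length") segs$length else segs$mean_score
    group <- summary$group[match(segs$protein_id, summary$protein_id)]
  }
  ok <- !is.na(values) & !is.na(group) & group != "intermediate"
  list(short = values[ok & group == "short"],
       long = values[ok & group == "long"])
}

#' Compare one aggregation metric between short- and long-living proteins
#'
#' Restricts the metric to the short (PSI <= 2) and long (PSI >= 5) groups
#' and applies both the Mann-Whitney and the Kolmogorov-Smirnov test.
#' `direction` is the sign of `median(short) - median(long)`: `+1` when the
#' short-living group sits at higher values.
#'
#' @param scan result of [summarize_proteome()].
#' @param psi named PSI vector (id -> PSI), e.g. from [read_psi_table()].
#' @param metric one of [COMPARISON_METRICS].
#' @param max_len optional maximum protein length; proteins longer than this
#'   are dropped before testing (length-restricted control).
#' @return One-row `data.frame`: `metric`, `n_short`, `n_long`,
#'   `median_short`, `median_long`, `mw_statistic`, `mw_p`, `ks_statistic`,
#'   `ks_p`, `direction`.
#' @export
compare_metric <- function(scan, psi, metric, max_len = NULL) {
  obs <- metric_observations(scan, psi, metric, max_len = max_len)
  for (g in c("short", "long")) {
    if (length(obs[[g]]) < 2L) {
      stop("fewer than 2 observations in the '", g, "' group for metric ",
           metric)
    }
  }
  mw <- mann_whitney(obs$short, obs$long)
  ks <- kolmogorov_smirnov(obs$short, obs$long)
  med_s <- stats::median(obs$short)
  med_l <- stats::median(obs$long)
  data.frame(metric = metric,
             n_short = length(obs$short), n_long = length(obs$long),
             median_short = med_s, median_long = med_l,
             mw_statistic = mw$statistic, mw_p = mw$p.value,
             ks_statistic = ks$statistic, ks_p = ks$p.value,
             direction = sign(med_s - med_l),
             stringsAsFactors = FALSE)
}

#' Compare all aggregation metrics between lifetime groups
#'
#' @inheritParams compare_metric
#' @param metrics metrics to test (default all of [COMPARISON_METRICS]).
#' @return A `data.frame` with one row per metric (see [compare_metric()]).
#'   No multiple-testing correction is applied across metrics; p-values are
#'   reported raw, per metric.
#' @export
compare_all_metrics <- function(scan, psi, metrics = COMPARISON_METRICS,
                                max_len = NULL) {
  out <- do.call(rbind, lapply(metrics, function(m) {
    compare_metric(scan, psi, m, max_len = max_len)
  }))
  rownames(out) <- NULL
  out
}

#' Length-restricted group comparison
#'
#' Repeats [compare_metric()] after excluding proteins longer than `max_len`
#' residues (default 300) — the control for the confound that long-living
#' proteins are on average longer than short-living ones.
#'
#' @inheritParams compare_metric
#' @param max_len maximum protein length retained.
#' @export
length_restricted_compare <- function(scan, psi, metric, max_len = 300L) {
  compare_metric(scan, psi, metric, max_len = max_len)
}

#' Mean aggregation load per protein-length bin and lifetime group
#'
#' @inheritParams compare_metric
#' @param bin_width protein-length bin width in residues (default 100).
#' @param min_n bins with fewer proteins than this are flagged `sparse`.
#' @return `data.frame`: `group`, `bin_start`, `bin_end`, `n`,
#'   `mean_normalized_score`, `sparse`.
#' @export
length_binned_profile <- function(scan, psi, bin_width = 100L, min_n = 5L) {
  summary <- scan$summary
  summary$group <- assign_lifetime_group(unname(psi[summary$protein_id]))
  summary <- summary[!is.na(summary$group) & summary$group != "intermediate", ,
                     drop = FALSE]
  bin <- (summary$length - 1L) %/% bin_width
  pieces <- list()
  for (g in c("short", "long")) {
    sel <- summary$group == g
    if (!any(sel)) next
    for (b in sort(unique(bin[sel]))) {
      rows <- sel & bin == b
      pieces[[length(pieces) + 1L]] <- data.frame(
        group = g, bin_start = b * bin_width + 1L,
        bin_end = (b + 1L) * bin_width, n = sum(rows),
        mean_normalized_score = mean(summary$normalized_score[rows]),
        sparse = sum(rows) < min_n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Expression-stratified comparison of aggregation load
#'
#' Controls for the possibility that a group difference in aggregation load
#' merely reflects different expression levels: proteins are binned by
#' normalized (log-scale) expression and the mean normalized aggregation
#' score is compared between lifetime groups *within* each bin. A genuine
#' lifetime effect persists in every populated bin; a pure expression
#' confound does not.
#'
#' @inheritParams compare_metric
#' @param expression named numeric vector (id -> normalized log expression).
#' @param bin_edges ascending numeric bin edges; default integer-width bins
#'   spanning the observed expression range.
#' @return `list(bins, expression_summary)`: `bins` has one row per
#'   (bin, group) with `n` and `mean_normalized_score` (`NaN`-free: empty
#'   cells keep `n = 0` and `NA` mean); `expression_summary` gives per-group
#'   `n`, `mean_expression`, `sd_expression` (the marginal density contrast).
#' @export
expression_stratified_compare <- function(scan, psi, expression,
                                          bin_edges = NULL) {
  summary <- scan$summary
  summary$group <- assign_lifetime_group(unname(psi[summary$protein_id]))
  summary$expression <- unname(expression[summary$protein_id])
  summary <- summary[!is.na(summary$group) & summary$group != "intermediate" &
                       !is.na(summary$expression), , drop = FALSE]
  if (nrow(summary) == 0L) stop("no proteins with both PSI group and expression")
  if (is.null(bin_edges)) {
    bin_edges <- seq(floor(min(summary$expression)),
                     ceiling(max(summary$expression)), by = 1)
    if (length(bin_edges) < 2L) bin_edges <- c(bin_edges, bin_edges + 1)
  }
  cuts <- cut(summary$expression, breaks = bin_edges, include.lowest = TRUE,
              right = FALSE)
  pieces <- list()
  for (b in levels(cuts)) {
    for (g in c("short", "long")) {
      rows <- !is.na(cuts) & cuts == b & summary$group == g
      pieces[[length(pieces) + 1L]] <- data.frame(
        bin = b, group = g, n = sum(rows),
        mean_normalized_score = if (any(rows)) {
          mean(summary$normalized_score[rows])
        } else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  bins <- do.call(rbind, pieces)
  rownames(bins) <- NULL
  expr_sum <- do.call(rbind, lapply(c("short", "long"), function(g) {
    x <- summary$expression[summary$group == g]
    data.frame(group = g, n = length(x), mean_expression = mean(x),
               sd_expression = stats::sd(x), stringsAsFactors = FALSE)
  }))
  list(bins = bins, expression_summary = expr_sum)
}
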