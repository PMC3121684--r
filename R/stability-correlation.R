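# Binned correlation between segment aggregation propensity and per-segment
# thermodynamic stability, per lifetime group.

# Product-moment correlation that is NA (not a warning) for degenerate input.
safe_cor <- function(x, y) {
  if (length(x) < 2L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Bin segments by propensity and correlate with thermodynamic stability
#'
#' For each lifetime group, computes the product-moment correlation between
#' segment aggregation propensity and thermodynamic stability on the raw
#' per-segment pairs (`r_raw`) and on per-bin means over propensity bins
#' (`r_bin`). Bin averaging de-noises a monotone trend, so `r_bin` typically
#' exceeds `r_raw` when the underlying relation is linear with additive
#' noise.
#'
#' Sign convention: input stability values are per-segment free-energy
#' contributions in kcal/mol with *lower = more stable*. By default the
#' correlation is computed against the negated values
#' (`negate_stability = TRUE`), so a positive correlation reads "more
#' aggregation-prone implies more stable". Bin mean stabilities are reported
#' in the original input units.
#'
#' @param segments `data.frame` with columns `propensity` (per-segment score,
#'   0-100), `stability` (kcal/mol) and `group`.
#' @param bin_edges ascending numeric edges over the propensity scale;
#'   default 10 equal-width bins over the observed propensity range (pooled
#'   across groups, so both groups share bins).
#' @param n_bins number of default equal-width bins.
#' @param negate_stability logical, see above.
#' @return `list(bins, correlations)`: `bins` has one row per (group, bin)
#'   with `n`, `mean_propensity`, `mean_stability`; `correlations` has one
#'   row per group with `n`, `r_raw`, `r_bin` (`r_bin` is `NA` when fewer
#'   than two bins are populated).
#' @export
bin_and_correlate <- function(segments, bin_edges = NULL, n_bins = 10L,
                              negate_stability = TRUE) {
  stopifnot(all(c("propensity", "stability", "group") %in% names(segments)))
  segments <- segments[!is.na(segments$propensity) &
                         !is.na(segments$stability) &
                         !is.na(segments$group), , drop = FALSE]
  groups <- unique(as.character(segments$group))
  for (g in groups) {
    if (sum(segments$group == g) < 3L) {
      stop("fewer than 3 segments with stability values in group '", g, "'")
    }
  }
  if (is.null(bin_edges)) {
    rng <- range(segments$propensity)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    bin_edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  }
  stopifnot(length(bin_edges) >= 2L, !is.unsorted(bin_edges))
  cuts <- cut(segments$propensity, breaks = bin_edges, include.lowest = TRUE)
  y <- if (negate_stability) -segments$stability else segments$stability
  bins <- list()
  cors <- list()
  for (g in groups) {
    sel <- segments$group == g
    for (b in levels(cuts)) {
      rows <- sel & !is.na(cuts) & cuts == b
      bins[[length(bins) + 1L]] <- data.frame(
        group = g, bin = b, n = sum(rows),
        mean_propensity = if (any(rows)) mean(segments$propensity[rows]) else NA_real_,
        mean_stability = if (any(rows)) mean(segments$stability[rows]) else NA_real_,
        stringsAsFactors = FALSE)
    }
    r_raw <- safe_cor(segments$propensity[sel], y[sel])
    bp <- tapply(segments$propensity[sel], droplevels(cuts[sel]), mean)
    by <- tapply(y[sel], droplevels(cuts[sel]), mean)
    r_bin <- safe_cor(as.numeric(bp), as.numeric(by))
    cors[[length(cors) + 1L]] <- data.frame(
      group = g, n = sum(sel), r_raw = r_raw, r_bin = r_bin,
      stringsAsFactors = FALSE)
  }
  bins <- do.call(rbind, bins)
  rownames(bins) <- NULL
  correlations <- do.call(rbind, cors)
  rownames(correlations) <- NULL
  list(bins = bins, correlations = correlations)
}

#' Join called segments with a stability table and lifetime groups
#'
#' Matches segments from [summarize_proteome()] to per-segment stability
#' values by exact (protein, start, end) coordinates and attaches the
#' two-group lifetime label, producing the input for [bin_and_correlate()].
#'
#' @param scan result of [summarize_proteome()].
#' @param stability `data.frame` from [read_stability_table()].
#' @param psi named PSI vector.
#' @return `data.frame` with `protein_id`, `start`, `end`, `propensity`,
#'   `stability`, `group` (short/long only).
#' @export
join_segment_stability <- function(scan, stability, psi) {
  segs <- scan$segments
  key <- paste(segs$protein_id, segs$start, segs$end)
  skey <- paste(stability$protein_id, stability$start, stability$end)
  idx <- match(key, skey)
  out <- data.frame(protein_id = segs$protein_id, start = segs$start,
                    end = segs$end, propensity = segs$mean_score,
                    stability = stability$stability[idx],
                    stringsAsFactors = FALSE)
  out$group <- as.character(
    assign_lifetime_group(unname(psi[out$protein_id])))
  out[!is.na(out$stability) & !is.na(out$group) &
        out$group != "intermediate", , drop = FALSE]
}
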