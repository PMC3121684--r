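# Segment calling from per-residue profiles, gatekeeper flank statistics, the
# four per-protein aggregation metrics, and a surrogate per-residue scorer.

#' Call aggregating segments from a per-residue profile
#'
#' An aggregating segment is a maximal run of at least `min_len` consecutive
#' residues whose per-residue propensity each strictly exceeds `threshold`
#' (default: five residues above 5 on the 0-100 scale). Runs are maximal:
#' the residues immediately before and after a segment, when they exist, do
#' not exceed the threshold.
#'
#' @param scores numeric vector of per-residue scores in `[0, 100]`.
#' @param min_len minimum run length (default 5).
#' @param threshold strict score threshold (default 5).
#' @return A `data.frame` with one row per segment, ascending `start`:
#'   `start`, `end` (1-based, inclusive), `length`, `sum_score`, `mean_score`.
#' @export
call_segments <- function(scores, min_len = 5L, threshold = 5) {
  stopifnot(is.numeric(scores), min_len >= 1L, threshold >= 0, threshold < 100)
  if (any(is.na(scores)) || any(scores < 0 | scores > 100)) {
    stop("scores must lie in [0, 100]")
  }
  empty <- data.frame(start = integer(0), end = integer(0), length = integer(0),
                      sum_score = numeric(0), mean_score = numeric(0))
  if (length(scores) == 0L) return(empty)
  r <- rle(scores > threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  if (!any(keep)) return(empty)
  starts <- starts[keep]
  ends <- ends[keep]
  sums <- vapply(seq_along(starts),
                 function(i) sum(scores[starts[i]:ends[i]]), numeric(1))
  data.frame(start = as.integer(starts), end = as.integer(ends),
             length = as.integer(ends - starts + 1L),
             sum_score = sums, mean_score = sums / (ends - starts + 1L))
}

#' Length-normalized aggregation score
#'
#' Total per-residue propensity divided by sequence length — the per-protein
#' "aggregation load".
#'
#' @param scores numeric per-residue score vector (non-empty).
#' @return A single number, `sum(scores) / length(scores)`.
#' @export
normalized_score <- function(scores) {
  if (length(scores) == 0L) stop("empty profile")
  sum(scores) / length(scores)
}

#' Gatekeeping flank positions of a segment
#'
#' The `flank_size` positions on each side of an aggregating segment
#' (default 5), truncated at the sequence ends; N- and C-side positions are
#' pooled, with no distinction between the two termini.
#'
#' @param start,end segment coordinates, 1-based inclusive.
#' @param seq_length length of the protein.
#' @param flank_size flank width on each side.
#' @return Integer vector of flank positions (possibly empty).
#' @export
flank_positions <- function(start, end, seq_length, flank_size = 5L) {
  stopifnot(start >= 1L, end <= seq_length, end >= start)
  left <- seq.int(max(1L, start - flank_size), start - 1L)
  left <- left[left >= 1L & left < start]
  right <- seq.int(end + 1L, min(seq_length, end + flank_size))
  right <- right[right > end & right <= seq_length]
  as.integer(c(left, right))
}

#' Gatekeeper frequency over the flanks of a protein's segments
#'
#' Fraction of flank positions occupied by a gatekeeper residue (P, R, K, E
#' or D), pooling all segments of the protein. Flank positions are pooled
#' with multiplicity one per segment-flank membership: a position falling in
#' the flanks of two adjacent segments contributes twice to the denominator.
#'
#' @param sequence the protein sequence (single string).
#' @param segments segment `data.frame` from [call_segments()].
#' @param flank_size flank width on each side.
#' @param gatekeepers residue set counted as gatekeepers.
#' @return Frequency in `[0, 1]`, or `NA` when there are no flank positions.
#' @export
gatekeeper_frequency <- function(sequence, segments, flank_size = 5L,
                                 gatekeepers = GATEKEEPER_RESIDUES) {
  stats <- flank_gatekeeper_stats(sequence, segments, flank_size, gatekeepers)
  if (sum(stats$n_flank) == 0L) return(NA_real_)
  sum(stats$n_gatekeepers) / sum(stats$n_flank)
}

# Per-segment flank size and gatekeeper count (pooled N- and C-side).
flank_gatekeeper_stats <- function(sequence, segments, flank_size = 5L,
                                   gatekeepers = GATEKEEPER_RESIDUES) {
  n <- nchar(sequence)
  letters <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n_flank <- integer(nrow(segments))
  n_gk <- integer(nrow(segments))
  for (i in seq_len(nrow(segments))) {
    pos <- flank_positions(segments$start[i], segments$end[i], n, flank_size)
    n_flank[i] <- length(pos)
    n_gk[i] <- sum(letters[pos] %in% gatekeepers)
  }
  data.frame(n_flank = n_flank, n_gatekeepers = n_gk)
}

# Residue propensity table for the surrogate scorer: hydrophobicity plus
# beta-sheet preference, with strongly negative entries for the gatekeepers
# so charged residues and proline suppress neighbouring scores. The "X"
# placeholder used in lenient parsing scores 0.
SURROGATE_PROPENSITY <- c(
  I = 4.5, V = 4.2, F = 4.0, L = 3.8, W = 2.6, M = 2.2, C = 2.0, Y = 1.8,
  A = 1.2, T = -0.5, S = -0.8, G = -1.0, H = -2.5, N = -3.0, Q = -3.0,
  P = -6.0, D = -6.0, E = -6.0, K = -6.0, R = -6.0, X = 0
)

#' Surrogate per-residue aggregation profile
#'
#' A deterministic stand-in scorer so the pipeline runs without an external
#' beta-aggregation predictor. It is **not** a statistical-mechanics
#' predictor: each residue's score is a centered sliding-window (width 5)
#' average of a fixed propensity table combining hydrophobicity and
#' beta-sheet preference, affine-rescaled so the table maximum maps to 100
#' and non-positive window means map to 0. Gatekeeper residues carry strongly
#' negative table entries, so prolines and charged residues suppress the
#' scores of every window containing them, mimicking the qualitative
#' behaviour of real predictors. Biological conclusions should be drawn from
#' real predictor output, not from this surrogate.
#'
#' @param sequence protein sequence (single string; lenient placeholder `"X"`
#'   allowed).
#' @param window centered window width (odd, default 5); windows are
#'   truncated at sequence ends.
#' @return Numeric vector of per-residue scores in `[0, 100]`.
#' @export
surrogate_profile <- function(sequence, window = 5L) {
  stopifnot(window >= 1L, window %% 2L == 1L)
  letters <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  if (!all(letters %in% names(SURROGATE_PROPENSITY))) {
    stop("invalid residue letter(s): ",
         paste(setdiff(letters, names(SURROGATE_PROPENSITY)), collapse = ","))
  }
  prop <- unname(SURROGATE_PROPENSITY[letters])
  n <- length(prop)
  half <- (window - 1L) %/% 2L
  means <- vapply(seq_len(n), function(i) {
    mean(prop[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
  100 * pmax(means, 0) / max(SURROGATE_PROPENSITY)
}

#' Summarize the aggregation propensity of one protein
#'
#' Composes segment calling, the length-normalized score, and the pooled
#' flank gatekeeper frequency into the four per-protein metrics: i) average
#' aggregation propensity (total score / length), ii) number of aggregating
#' segments, iii) their lengths, iv) their per-segment propensities.
#'
#' @param sequence protein sequence (single string).
#' @param scores per-residue profile matching the sequence length.
#' @param min_len,threshold see [call_segments()].
#' @param flank_size see [flank_positions()].
#' @return `list(summary = <1-row data.frame>, segments = <data.frame>)`;
#'   `segments` adds per-segment `n_flank` and `n_gatekeepers` columns.
#' @export
summarize_protein <- function(sequence, scores, min_len = 5L, threshold = 5,
                              flank_size = 5L) {
  if (nchar(sequence) != length(scores)) {
    stop("profile length (", length(scores),
         ") does not match sequence length (", nchar(sequence), ")")
  }
  segs <- call_segments(scores, min_len = min_len, threshold = threshold)
  fl <- flank_gatekeeper_stats(sequence, segs, flank_size)
  segs$n_flank <- fl$n_flank
  segs$n_gatekeepers <- fl$n_gatekeepers
  gk <- if (sum(segs$n_flank) > 0L) {
    sum(segs$n_gatekeepers) / sum(segs$n_flank)
  } else NA_real_
  list(
    summary = data.frame(
      length = nchar(sequence),
      normalized_score = normalized_score(scores),
      n_segments = nrow(segs),
      gatekeeper_frequency = gk
    ),
    segments = segs
  )
}

#' Summarize aggregation propensity across a proteome
#'
#' @param records protein-record `data.frame` (see [protein_records()]).
#' @param profiles named list of per-residue score vectors keyed by protein
#'   id, or `NULL` to score every sequence with [surrogate_profile()].
#' @param min_len,threshold,flank_size see [summarize_protein()].
#' @return `list(summary, segments)`: `summary` has one row per protein
#'   (`protein_id`, `length`, `normalized_score`, `n_segments`,
#'   `gatekeeper_frequency`); `segments` one row per called segment
#'   (`protein_id`, `start`, `end`, `length`, `mean_score`, `sum_score`,
#'   `n_flank`, `n_gatekeepers`).
#' @export
summarize_proteome <- function(records, profiles = NULL, min_len = 5L,
                               threshold = 5, flank_size = 5L) {
  if (is.null(profiles)) {
    profiles <- lapply(records$sequence, surrogate_profile)
    names(profiles) <- records$protein_id
  }
  missing <- setdiff(records$protein_id, names(profiles))
  if (length(missing)) {
    stop("no profile for: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  sums <- vector("list", nrow(records))
  segs <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    id <- records$protein_id[i]
    one <- summarize_protein(records$sequence[i], profiles[[id]],
                             min_len = min_len, threshold = threshold,
                             flank_size = flank_size)
    sums[[i]] <- cbind(protein_id = id, one$summary)
    if (nrow(one$segments)) segs[[i]] <- cbind(protein_id = id, one$segments)
  }
  segs <- segs[!vapply(segs, is.null, logical(1))]
  segments <- if (length(segs)) do.call(rbind, segs) else {
    data.frame(protein_id = character(0), start = integer(0), end = integer(0),
               length = integer(0), sum_score = numeric(0),
               mean_score = numeric(0), n_flank = integer(0),
               n_gatekeepers = integer(0))
  }
  rownames(segments) <- NULL
  summary <- do.call(rbind, sums)
  rownames(summary) <- NULL
  structure(list(summary = summary, segments = segments), class = "agscan_scan")
}

#' @export
print.agscan_scan <- function(x, ...) {
  cat("Aggregation scan:", nrow(x$summary), "proteins,",
      nrow(x$segments), "aggregating segments\n")
  cat(sprintf("  mean normalized score: %.3f\n",
              mean(x$summary$normalized_score)))
  gk <- x$summary$gatekeeper_frequency
  if (any(!is.na(gk))) {
    cat(sprintf("  mean flank gatekeeper frequency: %.3f\n",
                mean(gk, na.rm = TRUE)))
  }
  invisible(x)
}
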