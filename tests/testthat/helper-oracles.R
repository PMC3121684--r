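# Independent oracles and small fixture builders shared across the suite.

# Brute-force segment caller: tests every window for the defining predicate
# (all residues strictly above threshold, length >= min_len) plus maximality.
# Deliberately window-based, independent of the run-length implementation.
brute_segments <- function(scores, min_len = 5L, threshold = 5) {
  n <- length(scores)
  ok <- scores > threshold
  out <- list()
  for (s in seq_len(n)) {
    if (!ok[s]) next
    for (e in s:n) {
      if (!ok[e]) break
      len <- e - s + 1L
      if (len >= min_len && (s == 1L || !ok[s - 1L]) &&
          (e == n || !ok[e + 1L])) {
        out[[length(out) + 1L]] <- data.frame(
          start = s, end = e, length = len,
          sum_score = sum(scores[s:e]),
          mean_score = sum(scores[s:e]) / len)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), sum_score = numeric(0),
                      mean_score = numeric(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Random profile with atoms at 0 and at the threshold value, plus a
# continuous component — exercises strict threshold comparison.
random_profile <- function(n, threshold = 5) {
  u <- runif(n)
  scores <- runif(n, 0, 100)
  scores[u < 0.4] <- 0
  scores[u >= 0.4 & u < 0.6] <- threshold
  scores
}

# Exhaustive-enumeration Mann-Whitney oracle: every C(n+m, n) assignment of
# the pooled midranks to group a, two-sided p as twice the smaller tail.
exact_mw <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(na + nb, na)
  us <- colSums(matrix(r[combs], nrow = na)) - na * (na + 1) / 2
  eps <- 1e-9
  p <- min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
  list(statistic = u_obs, p.value = p)
}

# A minimal scan object (the list summarize_proteome() returns) built
# directly from per-protein values, for tests of the comparison layer that
# do not need sequences.
fake_scan <- function(protein_id, length, normalized_score,
                      n_segments = 0L, gatekeeper_frequency = NA_real_,
                      segments = NULL) {
  if (is.null(segments)) {
    segments <- data.frame(protein_id = character(0), start = integer(0),
                           end = integer(0), length = integer(0),
                           sum_score = numeric(0), mean_score = numeric(0),
                           n_flank = integer(0), n_gatekeepers = integer(0))
  }
  structure(list(
    summary = data.frame(protein_id = protein_id, length = length,
                         normalized_score = normalized_score,
                         n_segments = n_segments,
                         gatekeeper_frequency = gatekeeper_frequency,
                         stringsAsFactors = FALSE),
    segments = segments), class = "agscan_scan")
}

# Write a profile TSV in the dialect read_profile_file() expects.
write_profile_fixture <- function(path, scores,
                                  residues = rep("A", length(scores)),
                                  positions = seq_along(scores),
                                  score_col = "aggregation") {
  df <- data.frame(position = positions, residue = residues, s = scores)
  names(df)[3] <- score_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
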