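test_that("call_segments finds the worked maximal run", {
  scores <- c(rep(0, 5), c(8, 12, 30, 30, 12, 8), rep(0, 9))
  segs <- call_segments(scores)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$start, 6L)
  expect_equal(segs$end, 11L)
  expect_equal(segs$length, 6L)
  expect_equal(segs$sum_score, 100)
  expect_equal(segs$mean_score, 100 / 6)
  expect_equal(segs, brute_segments(scores))
})

test_that("call_segments applies the length rule and strict threshold", {
  expect_equal(nrow(call_segments(rep(0, 30))), 0L)
  # run of exactly 4 fails, run of exactly 5 passes
  expect_equal(nrow(call_segments(c(rep(0, 3), rep(50, 4), rep(0, 3)))), 0L)
  s5 <- call_segments(c(rep(0, 3), rep(50, 5), rep(0, 3)))
  expect_equal(s5$length, 5L)
  # a residue scoring exactly 5.0 splits an otherwise qualifying run
  scores <- c(rep(50, 5), 5.0, rep(50, 5))
  segs <- call_segments(scores)
  expect_equal(segs$start, c(1L, 7L))
  expect_equal(segs$end, c(5L, 11L))
  # whole-sequence run is called with both ends at the boundaries
  expect_equal(call_segments(rep(9, 7))$length, 7L)
})

test_that("call_segments equals the brute-force oracle on random profiles", {
  set.seed(101)
  for (i in 1:150) {
    scores <- random_profile(sample(1:120, 1))
    expect_equal(call_segments(scores), brute_segments(scores))
  }
})

test_that("called segments are sorted, disjoint and separated", {
  set.seed(13)
  for (i in 1:50) {
    scores <- random_profile(sample(20:200, 1))
    segs <- call_segments(scores)
    if (nrow(segs) < 2) next
    expect_false(is.unsorted(segs$start))
    expect_true(all(segs$start[-1] > segs$end[-nrow(segs)] + 1L))
    # at least one sub-threshold residue between consecutive segments
    gaps <- mapply(function(a, b) any(scores[(a + 1):(b - 1)] <= 5),
                   segs$end[-nrow(segs)], segs$start[-1])
    expect_true(all(gaps))
  }
})

test_that("normalized_score is the length-normalized total and is linear", {
  expect_equal(normalized_score(rep(0, 12)), 0)
  scores <- c(rep(0, 5), c(8, 12, 30, 30, 12, 8), rep(0, 9))
  expect_equal(normalized_score(scores), 5)
  expect_equal(normalized_score(rep(10, 33)), 10)
  expect_error(normalized_score(numeric(0)), "empty")
  set.seed(5)
  x <- runif(40, 0, 50)
  expect_equal(normalized_score(2 * x), 2 * normalized_score(x))
})

test_that("flank_positions pools both sides and clips at the termini", {
  expect_equal(flank_positions(6, 11, 20), c(1:5, 12:16))
  expect_equal(flank_positions(1, 6, 20), 7:11)     # N-terminal segment
  expect_equal(flank_positions(15, 20, 20), 10:14)  # C-terminal segment
  expect_equal(flank_positions(3, 18, 20), c(1:2, 19:20))
  expect_equal(flank_positions(1, 20, 20), integer(0))
})

test_that("gatekeeper_frequency counts P/R/K/E/D over pooled flanks", {
  seq1 <- "AAKAPVLVVVIEDAAAAAAA"
  segs <- data.frame(start = 6L, end = 11L)
  expect_equal(gatekeeper_frequency(seq1, segs), 0.4)
  expect_equal(gatekeeper_frequency(paste(rep("A", 20), collapse = ""), segs), 0)
  expect_equal(gatekeeper_frequency(paste(rep("K", 20), collapse = ""), segs), 1)
  # no segments -> no flank positions -> NA
  expect_true(is.na(gatekeeper_frequency(seq1, segs[0, , drop = FALSE])))
})

test_that("gatekeeper_frequency is invariant to segment order and pools
           overlapping flanks with multiplicity", {
  seq2 <- paste(rep("A", 40), collapse = "")
  segs <- data.frame(start = c(6L, 20L), end = c(11L, 27L))
  expect_equal(gatekeeper_frequency(seq2, segs),
               gatekeeper_frequency(seq2, segs[2:1, ]))
  # adjacent segments whose flanks overlap: position counted per membership
  seqK <- paste(c(rep("A", 5), rep("V", 5), "K", rep("V", 5), rep("A", 5)),
                collapse = "")
  segs2 <- data.frame(start = c(6L, 12L), end = c(10L, 16L))
  st <- summarize_protein(seqK, c(rep(0, 5), rep(50, 5), 0, rep(50, 5), rep(0, 5)))
  expect_equal(sum(st$segments$n_flank), 20L)  # 10 per segment, K in both
  expect_equal(st$summary$gatekeeper_frequency, 2 / 20)
})

test_that("surrogate profile is deterministic, bounded and symmetric", {
  polyA <- paste(rep("A", 30), collapse = "")
  p <- surrogate_profile(polyA)
  expect_true(all(p == p[1]))
  set.seed(3)
  s <- paste(sample(STANDARD_RESIDUES, 60, replace = TRUE), collapse = "")
  p1 <- surrogate_profile(s)
  expect_true(all(p1 >= 0 & p1 <= 100))
  rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(surrogate_profile(rev_s), rev(p1))
})

test_that("inserting a proline lowers every window containing it", {
  base <- paste(rep("V", 21), collapse = "")
  mut <- paste(c(rep("V", 10), "P", rep("V", 10)), collapse = "")
  p0 <- surrogate_profile(base)
  p1 <- surrogate_profile(mut)
  touched <- 9:13  # windows of width 5 containing position 11
  expect_true(all(p1[touched] < p0[touched]))
  expect_equal(p1[-c(touched)], p0[-c(touched)])
})

test_that("summarize_protein composes the per-protein metrics", {
  seq1 <- "AAKAPVLVVVIEDAAAAAAA"
  scores <- c(rep(0, 5), c(8, 12, 30, 30, 12, 8), rep(0, 9))
  res <- summarize_protein(seq1, scores)
  expect_equal(res$summary$n_segments, 1L)
  expect_equal(res$summary$normalized_score, 5)
  expect_equal(res$summary$gatekeeper_frequency, 0.4)
  expect_equal(res$segments$length, 6L)
  zero <- summarize_protein(seq1, rep(0, 20))
  expect_equal(zero$summary$n_segments, 0L)
  expect_equal(zero$summary$normalized_score, 0)
  expect_true(is.na(zero$summary$gatekeeper_frequency))
  expect_error(summarize_protein(seq1, rep(0, 19)), "match")
})

test_that("summarize_proteome pools flanks across two planted segments", {
  letters <- rep("A", 60)
  letters[11:16] <- "V"; letters[41:47] <- "I"
  letters[c(8, 18, 38)] <- "K"  # gatekeepers inside flanks
  seqs <- paste(letters, collapse = "")
  scores <- numeric(60); scores[11:16] <- 30; scores[41:47] <- 40
  rec <- protein_records("P1", seqs)
  scan <- summarize_proteome(rec, list(P1 = scores))
  expect_equal(scan$summary$n_segments, 2L)
  expect_equal(nrow(scan$segments), 2L)
  # brute recount of pooled flank gatekeepers
  fl <- c(flank_positions(11, 16, 60), flank_positions(41, 47, 60))
  expect_equal(scan$summary$gatekeeper_frequency,
               sum(letters[fl] == "K") / length(fl))
  expect_error(summarize_proteome(rec, list(Q9 = scores)), "no profile")
})
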