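# Synthetic proteome generator: sequences with planted aggregating segments,
# gatekeeper-populated flanks, PSI values, chaperone/disease labels,
# expression levels and per-segment stability values, with configurable
# group effect sizes and a truth log for every planted feature.

# Approximate background amino-acid frequencies of the human proteome.
BACKGROUND_AA_FREQ <- c(
  A = 0.070, R = 0.056, N = 0.036, D = 0.047, C = 0.023, E = 0.071,
  Q = 0.048, G = 0.066, H = 0.026, I = 0.043, L = 0.099, K = 0.057,
  M = 0.021, F = 0.037, P = 0.063, S = 0.083, T = 0.053, W = 0.012,
  Y = 0.027, V = 0.060
)

# Hydrophobic, beta-prone alphabet used for planted segment bodies.
SEGMENT_ALPHABET <- c("V", "I", "L", "F", "M", "W", "Y", "A")

#' Configuration for the synthetic proteome generator
#'
#' Defaults encode the study conditions the analysis assumes: 191 short- and
#' 420 long-living proteins after the membrane/extracellular filter, mean
#' protein lengths of about 263 (short) and 357 (long) residues, planted
#' aggregating segments that are longer and stronger in the short-living
#' group, a lower gatekeeper probability in short-living flanks, PSI drawn
#' uniformly within each group's interval, chaperone-binding probability
#' increasing with the PSI category, a modest expression shift between
#' groups, and per-segment stability linear in segment score with Gaussian
#' noise (lower stability value = more stable).
#'
#' @param n_short,n_long,n_intermediate group sizes; intermediate decoys get
#'   long-group sequence parameters and PSI in the excluded middle range.
#' @param length_meanlog,length_sdlog per-group log-normal parameters of
#'   protein length (residues); defaults target group means of 263 and 357.
#' @param min_length minimum protein length.
#' @param segments_per_protein per-group Poisson mean of planted segments.
#' @param segment_length_prob per-group geometric success probability; a
#'   planted segment has length `5 + rgeom(prob)`, so smaller prob = longer
#'   segments.
#' @param segment_score_level per-group mean planted per-residue score
#'   (0-100 scale); each segment draws its level from
#'   `Normal(level, segment_score_sd)` truncated to `[10, 100]` and assigns
#'   it to every residue of the segment.
#' @param segment_score_sd between-segment spread of the planted level.
#' @param gatekeeper_flank_prob per-group probability that a flank position
#'   carries a gatekeeper residue (P, R, K, E, D).
#' @param psi_range named list of per-group PSI sampling intervals.
#' @param chaperone_binder_prob binder probability per four-category PSI
#'   class (see [assign_four_category()]).
#' @param disease_prob per-group probability of a deposition-disease label.
#' @param expression_mean,expression_sd per-group normal parameters of
#'   log-scale expression.
#' @param stability_alpha,stability_sigma per-segment stability is
#'   `-(stability_alpha * score_level) + Normal(0, stability_sigma)` kcal/mol
#'   (more aggregation-prone segments are more stable).
#' @param background_noise if `TRUE`, background residues get sub-threshold
#'   jitter uniform in `[0, 5)` instead of 0, exercising threshold
#'   strictness.
#' @param membrane_prob probability a protein is tagged `"KW-472"` (for
#'   exercising the keyword filter; default 0).
#' @param flank_size flank width used when planting gatekeepers.
#' @param null_effect if `TRUE`, every per-group parameter is set to the
#'   long-group value, so the two groups are statistically identical and
#'   group labels are exchangeable (null calibration).
#' @return A list of class `"agscan_config"`.
#' @export
synthetic_config <- function(n_short = 191L, n_long = 420L,
                             n_intermediate = 0L,
                             length_meanlog = c(short = log(263) - 0.125,
                                                long = log(357) - 0.125),
                             length_sdlog = c(short = 0.5, long = 0.5),
                             min_length = 60L,
                             segments_per_protein = c(short = 3, long = 3),
                             segment_length_prob = c(short = 0.25, long = 0.4),
                             segment_score_level = c(short = 40, long = 30),
                             segment_score_sd = 5,
                             gatekeeper_flank_prob = c(short = 0.25,
                                                       long = 0.35),
                             psi_range = list(short = c(1, 2),
                                              long = c(5, 7),
                                              intermediate = c(2.2, 4.8)),
                             chaperone_binder_prob = c(short = 0.10,
                                                       medium = 0.18,
                                                       long = 0.25,
                                                       extra_long = 0.30),
                             disease_prob = c(short = 15 / 191,
                                              long = 1 / 420),
                             expression_mean = c(short = 6.5, long = 7.0),
                             expression_sd = c(short = 1.0, long = 1.0),
                             stability_alpha = 0.05, stability_sigma = 1.0,
                             background_noise = FALSE, membrane_prob = 0,
                             flank_size = 5L, null_effect = FALSE) {
  cfg <- list(n_short = as.integer(n_short), n_long = as.integer(n_long),
              n_intermediate = as.integer(n_intermediate),
              length_meanlog = length_meanlog, length_sdlog = length_sdlog,
              min_length = as.integer(min_length),
              segments_per_protein = segments_per_protein,
              segment_length_prob = segment_length_prob,
              segment_score_level = segment_score_level,
              segment_score_sd = segment_score_sd,
              gatekeeper_flank_prob = gatekeeper_flank_prob,
              psi_range = psi_range,
              chaperone_binder_prob = chaperone_binder_prob,
              disease_prob = disease_prob,
              expression_mean = expression_mean,
              expression_sd = expression_sd,
              stability_alpha = stability_alpha,
              stability_sigma = stability_sigma,
              background_noise = isTRUE(background_noise),
              membrane_prob = membrane_prob,
              flank_size = as.integer(flank_size))
  if (isTRUE(null_effect)) {
    for (f in c("length_meanlog", "length_sdlog", "segments_per_protein",
                "segment_length_prob", "segment_score_level",
                "gatekeeper_flank_prob", "disease_prob", "expression_mean",
                "expression_sd")) {
      cfg[[f]][] <- cfg[[f]][["long"]]
    }
  }
  probs <- c(cfg$segment_length_prob, cfg$gatekeeper_flank_prob,
             cfg$chaperone_binder_prob, cfg$disease_prob, cfg$membrane_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(cfg$segment_length_prob <= 0)) stop("segment_length_prob must be > 0")
  if (cfg$min_length < 5L) {
    stop("min_length must be at least 5 (a planted segment cannot exceed ",
         "the protein)")
  }
  if (any(cfg$segment_score_level <= 5 | cfg$segment_score_level > 100)) {
    stop("segment_score_level must lie in (5, 100]")
  }
  structure(cfg, class = "agscan_config")
}

# Group-indexed parameter lookup: intermediate decoys use long-group values.
group_param <- function(cfg, field, group) {
  g <- if (group == "intermediate") "long" else group
  cfg[[field]][[g]]
}

#' Generate a synthetic proteome
#'
#' Produces sequences built from background residue frequencies with planted
#' aggregating segments (hydrophobic bodies, per-residue profile scores set
#' to the planted level, flanks populated with gatekeepers at the configured
#' probability), plus PSI values, annotations, expression levels, a
#' per-segment stability table, and a truth log recording every planted
#' segment. Deterministic given `(config, seed)`; the caller's RNG state is
#' left untouched.
#'
#' Planted segments are separated by at least `2 * flank_size + 1` background
#' residues so that flanks never overlap a neighbouring segment body;
#' sampled segments that cannot be placed within the drawn protein length
#' are dropped (the truth log records placed segments only).
#'
#' @param config an [synthetic_config()] object.
#' @param seed integer seed controlling all randomness.
#' @return A list of class `"agscan_proteome"`: `records` (protein-record
#'   `data.frame` including psi, keywords, labels, expression), `profiles`
#'   (named list of per-residue scores), `stability` (per-segment stability
#'   table), `truth` (planted-segment log with `protein_id`, `group`,
#'   `start`, `end`, `length`, `score_level`), `config`, `seed`.
#' @export
generate_proteome <- function(config, seed) {
  stopifnot(inherits(config, "agscan_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  groups <- rep(c("short", "long", "intermediate"),
                times = c(config$n_short, config$n_long, config$n_intermediate))
  n_prot <- length(groups)
  ids <- sprintf("SYN%04d", seq_len(n_prot))
  aa <- names(BACKGROUND_AA_FREQ)
  bg_freq <- BACKGROUND_AA_FREQ / sum(BACKGROUND_AA_FREQ)
  non_gk <- setdiff(aa, GATEKEEPER_RESIDUES)
  non_gk_freq <- bg_freq[non_gk] / sum(bg_freq[non_gk])
  gap <- 2L * config$flank_size + 1L

  sequences <- character(n_prot)
  profiles <- vector("list", n_prot)
  truth <- vector("list", n_prot)

  for (i in seq_len(n_prot)) {
    g <- groups[i]
    n <- max(config$min_length,
             round(stats::rlnorm(1, group_param(config, "length_meanlog", g),
                                 group_param(config, "length_sdlog", g))))
    k <- stats::rpois(1, group_param(config, "segments_per_protein", g))
    lens <- if (k > 0) {
      5L + stats::rgeom(k, group_param(config, "segment_length_prob", g))
    } else integer(0)
    # drop segments until the set fits with the minimum inter-segment gap
    while (k > 0L && sum(lens) + (k - 1L) * gap > n) {
      k <- k - 1L
      lens <- lens[seq_len(k)]
    }
    letters <- sample(aa, n, replace = TRUE, prob = bg_freq)
    scores <- if (config$background_noise) {
      stats::runif(n, 0, 5) * 0.999
    } else numeric(n)

    if (k > 0L) {
      extra <- n - sum(lens) - (k - 1L) * gap
      alloc <- if (extra > 0L) {
        tabulate(sample.int(k + 1L, extra, replace = TRUE), k + 1L)
      } else integer(k + 1L)
      starts <- integer(k)
      pos <- 0L
      for (j in seq_len(k)) {
        pos <- pos + alloc[j] + if (j > 1L) gap else 0L
        starts[j] <- pos + 1L
        pos <- pos + lens[j]
      }
      levels_j <- pmin(100, pmax(10, stats::rnorm(
        k, group_param(config, "segment_score_level", g),
        config$segment_score_sd)))
      p_gk <- group_param(config, "gatekeeper_flank_prob", g)
      for (j in seq_len(k)) {
        body <- starts[j]:(starts[j] + lens[j] - 1L)
        letters[body] <- sample(SEGMENT_ALPHABET, lens[j], replace = TRUE)
        scores[body] <- levels_j[j]
        fl <- flank_positions(starts[j], starts[j] + lens[j] - 1L, n,
                              config$flank_size)
        if (length(fl)) {
          is_gk <- stats::runif(length(fl)) < p_gk
          if (any(is_gk)) {
            letters[fl[is_gk]] <- sample(GATEKEEPER_RESIDUES, sum(is_gk),
                                         replace = TRUE)
          }
          if (any(!is_gk)) {
            letters[fl[!is_gk]] <- sample(non_gk, sum(!is_gk),
                                          replace = TRUE, prob = non_gk_freq)
          }
        }
      }
      truth[[i]] <- data.frame(protein_id = ids[i], group = g,
                               start = starts,
                               end = starts + lens - 1L,
                               length = lens, score_level = levels_j,
                               stringsAsFactors = FALSE)
    }
    sequences[i] <- paste(letters, collapse = "")
    profiles[[i]] <- scores
  }
  names(profiles) <- ids

  psi <- vapply(groups, function(g) {
    r <- config$psi_range[[g]]
    stats::runif(1, r[1], r[2])
  }, numeric(1), USE.NAMES = FALSE)
  expression <- vapply(seq_len(n_prot), function(i) {
    stats::rnorm(1, group_param(config, "expression_mean", groups[i]),
                 group_param(config, "expression_sd", groups[i]))
  }, numeric(1))
  keywords <- ifelse(stats::runif(n_prot) < config$membrane_prob,
                     "KW-472", "")
  category <- as.character(assign_four_category(psi))
  binder <- ifelse(
    stats::runif(n_prot) < config$chaperone_binder_prob[category],
    "yes", "no")
  disease <- vapply(seq_len(n_prot), function(i) {
    p <- group_param(config, "disease_prob", groups[i])
    if (stats::runif(1) < p) "yes" else "no"
  }, character(1))

  records <- protein_records(protein_id = ids, sequence = sequences,
                             psi = psi, keywords = keywords,
                             chaperone_binder = binder,
                             disease_deposition = disease,
                             expression = expression)
  records$group <- groups

  truth <- truth[!vapply(truth, is.null, logical(1))]
  truth <- if (length(truth)) do.call(rbind, truth) else {
    data.frame(protein_id = character(0), group = character(0),
               start = integer(0), end = integer(0), length = integer(0),
               score_level = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(truth) <- NULL
  stability <- data.frame(
    protein_id = truth$protein_id, start = truth$start, end = truth$end,
    stability = -(config$stability_alpha * truth$score_level) +
      stats::rnorm(nrow(truth), 0, config$stability_sigma),
    stringsAsFactors = FALSE)

  structure(list(records = records, profiles = profiles,
                 stability = stability, truth = truth, config = config,
                 seed = as.integer(seed)),
            class = "agscan_proteome")
}

#' @export
print.agscan_proteome <- function(x, ...) {
  cat("Synthetic proteome:", nrow(x$records), "proteins (",
      sum(x$records$group == "short"), "short /",
      sum(x$records$group == "long"), "long /",
      sum(x$records$group == "intermediate"), "intermediate ),",
      nrow(x$truth), "planted segments, seed", x$seed, "\n")
  invisible(x)
}

# Full-precision numeric formatting so TSV round-trips are exact.
fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic proteome as a fixture file set
#'
#' Emits every input format the pipeline consumes: `proteins.fasta`,
#' `psi.tsv`, `annotations.tsv`, `expression.tsv`, `stability.tsv`, a
#' `profiles/` directory with one per-residue TSV per protein, and the
#' planted-segment `truth.tsv`. Numeric columns are written at full
#' precision so a read-back reproduces the in-memory objects exactly.
#'
#' @param proteome an [generate_proteome()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_set <- function(proteome, dir) {
  stopifnot(inherits(proteome, "agscan_proteome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir)
  rec <- proteome$records
  write_fasta(rec, file.path(dir, "proteins.fasta"))
  write_tsv_plain(data.frame(protein_id = rec$protein_id,
                             psi = fmt_num(rec$psi)),
                  file.path(dir, "psi.tsv"))
  write_tsv_plain(data.frame(protein_id = rec$protein_id,
                             keywords = rec$keywords,
                             chaperone_binder = rec$chaperone_binder,
                             disease_deposition = rec$disease_deposition),
                  file.path(dir, "annotations.tsv"))
  write_tsv_plain(data.frame(protein_id = rec$protein_id,
                             expression = fmt_num(rec$expression)),
                  file.path(dir, "expression.tsv"))
  stab <- proteome$stability
  write_tsv_plain(data.frame(protein_id = stab$protein_id,
                             start = stab$start, end = stab$end,
                             stability = fmt_num(stab$stability)),
                  file.path(dir, "stability.tsv"))
  tr <- proteome$truth
  write_tsv_plain(data.frame(protein_id = tr$protein_id, group = tr$group,
                             start = tr$start, end = tr$end,
                             length = tr$length,
                             score_level = fmt_num(tr$score_level)),
                  file.path(dir, "truth.tsv"))
  prof_dir <- file.path(dir, "profiles")
  dir.create(prof_dir, showWarnings = FALSE)
  for (i in seq_len(nrow(rec))) {
    id <- rec$protein_id[i]
    scores <- proteome$profiles[[id]]
    write_tsv_plain(
      data.frame(position = seq_along(scores),
                 residue = strsplit(rec$sequence[i], "", fixed = TRUE)[[1]],
                 aggregation = fmt_num(scores)),
      file.path(prof_dir, paste0(id, ".tsv")))
  }
  invisible(dir)
}

#' Read a fixture set back into memory
#'
#' Inverse of [write_fixture_set()] (the truth log is read too when
#' present).
#'
#' @param dir fixture directory.
#' @param strict sequence alphabet handling, see [protein_records()].
#' @return A list with `records`, `profiles`, `stability`, `truth`.
#' @export
read_fixture_set <- function(dir, strict = TRUE) {
  rec <- read_fasta(file.path(dir, "proteins.fasta"), strict = strict)
  psi <- read_psi_table(file.path(dir, "psi.tsv"))
  ann <- read_annotation_table(file.path(dir, "annotations.tsv"))
  expr <- read_expression_table(file.path(dir, "expression.tsv"))
  idx <- match(rec$protein_id, ann$protein_id)
  rec$psi <- unname(psi[rec$protein_id])
  rec$keywords <- ann$keywords[idx]
  rec$chaperone_binder <- ann$chaperone_binder[idx]
  rec$disease_deposition <- ann$disease_deposition[idx]
  rec$expression <- unname(expr[rec$protein_id])
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) {
    df <- read_tsv_checked(truth_path,
                           c("protein_id", "group", "start", "end", "length",
                             "score_level"))
    data.frame(protein_id = df$protein_id, group = df$group,
               start = as.integer(df$start), end = as.integer(df$end),
               length = as.integer(df$length),
               score_level = as.numeric(df$score_level),
               stringsAsFactors = FALSE)
  } else NULL
  list(records = rec,
       profiles = read_profile_dir(file.path(dir, "profiles")),
       stability = read_stability_table(file.path(dir, "stability.tsv")),
       truth = truth)
}
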