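# End-to-end analysis runner: scan, group comparisons with significance
# flags, enrichment, stability bins, and a machine-readable run manifest.

#' Two-tier significance flags for group comparisons
#'
#' `"++"`/`"--"` mark distributions significantly (p < 0.001) shifted to
#' higher/lower values in the short-living group relative to the long-living
#' reference, `"+"`/`"-"` the same at p < 0.01, `"0"` otherwise. Direction
#' is the sign of `median(short) - median(long)`.
#'
#' @param p two-sided p-values.
#' @param direction sign of the median difference (+1, 0, -1).
#' @return Character vector of flags.
#' @export
significance_flag <- function(p, direction) {
  out <- rep("0", length(p))
  hi <- !is.na(p) & p < 0.01 & direction != 0
  out[hi & direction > 0] <- "+"
  out[hi & direction < 0] <- "-"
  vh <- !is.na(p) & p < 0.001 & direction != 0
  out[vh & direction > 0] <- "++"
  out[vh & direction < 0] <- "--"
  out
}

report_log <- function(verbose, ...) {
  if (verbose) message(format(Sys.time(), "%H:%M:%S"), " agscan: ", ...)
}

#' Run the full aggregation-vs-turnover analysis
#'
#' Reads the inputs, removes membrane/extracellular proteins, scans for
#' aggregating segments (from per-residue profile files or the surrogate
#' scorer), and writes: a per-protein summary and per-segment table; the
#' metric-comparison table (all proteins and the length-restricted control)
#' with two-tier significance flags; the chaperone-binding enrichment and
#' deposition-disease tally (when annotations are given); expression-
#' stratified means (when expression is given); stability bins and
#' correlations (when a stability table is given); and a JSON run manifest
#' with package version, parameters, input checksums and output files.
#' Stages whose optional inputs are missing are skipped with a warning.
#'
#' @param fasta path to the FASTA file of sequences.
#' @param psi path to the PSI TSV.
#' @param out_dir output directory (created if needed).
#' @param profiles_dir directory of per-residue profile TSVs, or `NULL` to
#'   use [surrogate_profile()].
#' @param annotations,expression,stability optional paths to the annotation,
#'   expression and per-segment stability TSVs.
#' @param min_len,threshold,flank_size segment-calling parameters.
#' @param max_len protein-length cutoff of the length-restricted control.
#' @param score_col profile file score column name.
#' @param strict sequence alphabet handling, see [protein_records()].
#' @param verbose log progress to standard error.
#' @return Invisibly, a list with the computed tables and `manifest`.
#' @export
run_full_analysis <- function(fasta, psi, out_dir, profiles_dir = NULL,
                              annotations = NULL, expression = NULL,
                              stability = NULL, min_len = 5L, threshold = 5,
                              flank_size = 5L, max_len = 300L,
                              score_col = "aggregation", strict = TRUE,
                              verbose = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- c(fasta = fasta, psi = psi)
  if (!is.null(profiles_dir)) inputs <- c(inputs, profiles_dir = profiles_dir)
  if (!is.null(annotations)) inputs <- c(inputs, annotations = annotations)
  if (!is.null(expression)) inputs <- c(inputs, expression = expression)
  if (!is.null(stability)) inputs <- c(inputs, stability = stability)

  report_log(verbose, "reading sequences from ", fasta)
  records <- read_fasta(fasta, strict = strict)
  psi_map <- read_psi_table(psi)
  records$psi <- unname(psi_map[records$protein_id])

  ann <- NULL
  if (!is.null(annotations)) {
    ann <- read_annotation_table(annotations)
    idx <- match(records$protein_id, ann$protein_id)
    records$keywords <- ifelse(is.na(idx), "", ann$keywords[idx])
    records$chaperone_binder <- ifelse(is.na(idx), "unknown",
                                       ann$chaperone_binder[idx])
    records$disease_deposition <- ifelse(is.na(idx), "unknown",
                                         ann$disease_deposition[idx])
  }
  parts <- filter_membrane_extracellular(records)
  report_log(verbose, "keyword filter removed ", nrow(parts$removed),
             " membrane/extracellular proteins; ", nrow(parts$kept), " kept")
  records <- parts$kept

  profiles <- if (!is.null(profiles_dir)) {
    report_log(verbose, "reading per-residue profiles from ", profiles_dir)
    read_profile_dir(profiles_dir, score_col = score_col)
  } else {
    report_log(verbose, "no profiles given; using the surrogate scorer")
    NULL
  }
  scan <- summarize_proteome(records, profiles, min_len = min_len,
                             threshold = threshold, flank_size = flank_size)

  outputs <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_tsv_plain(df, path)
    outputs <<- c(outputs, path)
    path
  }
  emit(scan$summary, "summary.tsv")
  segs_out <- scan$segments
  names(segs_out)[names(segs_out) == "n_gatekeepers"] <- "flank_gatekeepers"
  names(segs_out)[names(segs_out) == "n_flank"] <- "flank_size"
  emit(segs_out, "segments.tsv")

  tables <- list(summary = scan$summary, segments = scan$segments)

  comparison <- tryCatch({
    full <- compare_all_metrics(scan, psi_map)
    full$analysis <- "all"
    restr <- compare_all_metrics(scan, psi_map, max_len = max_len)
    restr$analysis <- paste0("length_le_", max_len)
    comp <- rbind(full, restr)
    comp$mw_flag <- significance_flag(comp$mw_p, comp$direction)
    comp$ks_flag <- significance_flag(comp$ks_p, comp$direction)
    comp
  }, error = function(e) {
    warning("comparison stage skipped: ", conditionMessage(e), call. = FALSE)
    NULL
  })
  if (!is.null(comparison)) {
    emit(comparison, "comparison.tsv")
    tables$comparison <- comparison
  }

  if (!is.null(ann)) {
    enr <- tryCatch(chaperone_enrichment(psi_map, records),
                    error = function(e) {
                      warning("enrichment stage skipped: ",
                              conditionMessage(e), call. = FALSE)
                      NULL
                    })
    if (!is.null(enr)) {
      emit(enr, "enrichment.tsv")
      tables$enrichment <- enr
    }
    tal <- disease_category_tally(records)
    tal_df <- rbind(tal$table,
                    data.frame(category = "short_medium",
                               n = tal$short_medium))
    emit(tal_df, "disease_tally.tsv")
    tables$disease_tally <- tal
  } else {
    report_log(verbose, "no annotation table; enrichment and disease stages skipped")
  }

  if (!is.null(expression)) {
    expr_map <- read_expression_table(expression)
    strat <- tryCatch(expression_stratified_compare(scan, psi_map, expr_map),
                      error = function(e) {
                        warning("expression stage skipped: ",
                                conditionMessage(e), call. = FALSE)
                        NULL
                      })
    if (!is.null(strat)) {
      emit(strat$bins, "expression_strata.tsv")
      emit(strat$expression_summary, "expression_summary.tsv")
      tables$expression <- strat
    }
  }

  if (!is.null(stability)) {
    stab <- read_stability_table(stability)
    res <- tryCatch({
      joined <- join_segment_stability(scan, stab, psi_map)
      bin_and_correlate(joined)
    }, error = function(e) {
      warning("stability stage skipped: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(res)) {
      emit(res$bins, "stability_bins.tsv")
      emit(res$correlations, "stability_correlations.tsv")
      tables$stability <- res
    }
  }

  manifest <- list(
    package = "agscan",
    version = as.character(utils::packageVersion("agscan")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    parameters = list(min_len = min_len, threshold = threshold,
                      flank_size = flank_size, max_len = max_len,
                      score_col = score_col, strict = strict),
    inputs = lapply(stats::setNames(as.list(inputs), names(inputs)),
                    function(p) {
                      if (dir.exists(p)) list(path = p, type = "directory")
                      else list(path = p,
                                md5 = unname(tools::md5sum(p)))
                    }),
    outputs = basename(c(outputs, file.path(out_dir, "manifest.json")))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  tables$manifest <- manifest
  report_log(verbose, "wrote ", length(manifest$outputs), " outputs to ",
             out_dir)
  invisible(tables)
}
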