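# Core data model: protein records, per-residue aggregation profiles, and the
# tab-delimited readers for PSI, annotation, expression and stability tables.

#' Gatekeeper residues
#'
#' The five aggregation-opposing residues counted as gatekeepers in flank
#' analyses: proline (beta-breaker), arginine, lysine (charge and burial
#' entropy), glutamate and aspartate (charge repulsion).
#' @export
GATEKEEPER_RESIDUES <- c("P", "R", "K", "E", "D")

#' @rdname GATEKEEPER_RESIDUES
#' @export
STANDARD_RESIDUES <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Non-standard letters tolerated in lenient mode.
AMBIGUOUS_RESIDUES <- c("B", "Z", "X", "U", "O")

#' Construct a table of protein records
#'
#' A protein record couples a sequence with the per-protein covariates used
#' downstream: PSI (protein stability index, 1-7, higher = slower turnover),
#' annotation keywords, chaperone-binder and deposition-disease labels, and a
#' normalized (log-scale) expression level.
#'
#' @param protein_id character vector of unique identifiers.
#' @param sequence character vector of amino-acid sequences (one-letter codes).
#' @param psi numeric PSI values in `[1, 7]`, `NA` when unmeasured.
#' @param keywords character vector of semicolon-joined annotation keyword
#'   codes (e.g. `"KW-472;KW-0272"`), `""` for none.
#' @param chaperone_binder,disease_deposition character, one of `"yes"`,
#'   `"no"`, `"unknown"`.
#' @param expression numeric normalized log-scale expression, `NA` if absent.
#' @param strict logical; if `TRUE` (default) sequences may contain only the
#'   20 standard residues. If `FALSE`, the ambiguity codes B/Z/X/U/O are
#'   replaced by the placeholder `"X"`, which is scored 0 by the surrogate
#'   scorer and never counted as a gatekeeper.
#' @return A `data.frame` with one row per protein and the columns above.
#' @export
protein_records <- function(protein_id, sequence, psi = NA_real_,
                            keywords = "", chaperone_binder = "unknown",
                            disease_deposition = "unknown",
                            expression = NA_real_, strict = TRUE) {
  protein_id <- as.character(protein_id)
  sequence <- toupper(as.character(sequence))
  if (anyDuplicated(protein_id)) {
    stop("duplicate protein ids: ",
         paste(unique(protein_id[duplicated(protein_id)]), collapse = ", "))
  }
  if (any(nchar(sequence) < 1L)) stop("empty sequence for: ",
                                      paste(protein_id[nchar(sequence) < 1L], collapse = ", "))
  sequence <- vapply(sequence, sanitize_sequence, character(1), strict = strict,
                     USE.NAMES = FALSE)
  psi <- as.numeric(psi)
  bad_psi <- !is.na(psi) & (psi < 1 | psi > 7)
  if (any(bad_psi)) {
    stop("PSI outside [1, 7] for: ",
         paste(protein_id[bad_psi], collapse = ", "))
  }
  tri <- function(x, what) {
    x <- as.character(x)
    ok <- x %in% c("yes", "no", "unknown")
    if (!all(ok)) stop(what, " must be yes/no/unknown")
    x
  }
  data.frame(
    protein_id = protein_id,
    sequence = sequence,
    length = nchar(sequence),
    psi = rep_len(psi, length(protein_id)),
    keywords = rep_len(as.character(keywords), length(protein_id)),
    chaperone_binder = rep_len(tri(chaperone_binder, "chaperone_binder"),
                               length(protein_id)),
    disease_deposition = rep_len(tri(disease_deposition, "disease_deposition"),
                                 length(protein_id)),
    expression = rep_len(as.numeric(expression), length(protein_id)),
    stringsAsFactors = FALSE
  )
}

# Validate one sequence against the residue alphabet; lenient mode maps
# ambiguity codes to the "X" placeholder.
sanitize_sequence <- function(seq, strict = TRUE) {
  letters <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- !(letters %in% STANDARD_RESIDUES)
  if (!any(bad)) return(seq)
  if (strict) {
    stop("non-standard residue(s) ",
         paste(unique(letters[bad]), collapse = ","),
         " in sequence (use strict = FALSE for lenient handling)")
  }
  unknown <- bad & !(letters %in% AMBIGUOUS_RESIDUES)
  if (any(unknown)) {
    stop("invalid residue letter(s): ", paste(unique(letters[unknown]), collapse = ","))
  }
  letters[bad] <- "X"
  paste(letters, collapse = "")
}

#' Read protein sequences from a FASTA file
#'
#' @param path path to a FASTA file of amino-acid sequences.
#' @param strict see [protein_records()].
#' @return A protein-record `data.frame`; ids are the first
#'   whitespace-delimited token of each header, input order preserved.
#'   An empty file yields a zero-row table.
#' @export
read_fasta <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) {
    return(protein_records(character(0), character(0)))
  }
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!startsWith(first, ">")) {
    stop("malformed FASTA at line 1 of ", path, ": expected '>' header")
  }
  set <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  protein_records(protein_id = ids,
                  sequence = as.character(set),
                  strict = strict)
}

#' Write protein sequences to a FASTA file
#'
#' @param records protein-record `data.frame`.
#' @param path output path.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::AAStringSet(records$sequence)
  names(set) <- records$protein_id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Shared strict TSV reader: UTF-8, tab-separated, '#' comments, header required.
read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(path, ": missing required column(s): ", paste(missing, collapse = ", "))
  }
  df
}

as_numeric_checked <- function(x, what, path) {
  out <- suppressWarnings(as.numeric(x))
  if (any(is.na(out) & !(x %in% c("", "NA")))) {
    stop(path, ": non-numeric ", what, " value(s): ",
         paste(utils::head(x[is.na(out) & x != "NA"], 3), collapse = ", "))
  }
  out
}

#' Read a PSI table
#'
#' @param path TSV with columns `protein_id`, `psi`.
#' @return Named numeric vector mapping protein id to PSI.
#' @export
read_psi_table <- function(path) {
  df <- read_tsv_checked(path, c("protein_id", "psi"))
  if (anyDuplicated(df$protein_id)) {
    stop(path, ": duplicate protein ids: ",
         paste(unique(df$protein_id[duplicated(df$protein_id)]), collapse = ", "))
  }
  psi <- as_numeric_checked(df$psi, "psi", path)
  bad <- !is.na(psi) & (psi < 1 | psi > 7)
  if (any(bad)) {
    stop(path, ": PSI outside [1, 7] for: ",
         paste(df$protein_id[bad], collapse = ", "))
  }
  stats::setNames(psi, df$protein_id)
}

#' Read a per-residue aggregation-propensity profile file
#'
#' Parses tab-delimited per-residue predictor output: one row per residue with
#' at least a position column, a residue letter column, and a named
#' beta-aggregation score column on the 0-100 scale.
#'
#' @param path profile file path.
#' @param score_col name of the score column (the "dialect"); default
#'   `"aggregation"`.
#' @return Numeric vector of per-residue scores in file order.
#' @export
read_profile_file <- function(path, score_col = "aggregation") {
  df <- read_tsv_checked(path, c("position", "residue", score_col))
  pos <- as_numeric_checked(df$position, "position", path)
  if (nrow(df) == 0L) stop(path, ": empty profile")
  if (!identical(as.integer(pos), seq_len(nrow(df)))) {
    stop(path, ": positions must be consecutive starting at 1")
  }
  scores <- as_numeric_checked(df[[score_col]], score_col, path)
  if (any(is.na(scores)) || any(scores < 0 | scores > 100)) {
    stop(path, ": score outside [0, 100]")
  }
  scores
}

#' Read a directory of per-residue profile files
#'
#' @param dir directory containing one `<protein_id>.tsv` per protein.
#' @param score_col passed to [read_profile_file()].
#' @return Named list of numeric score vectors.
#' @export
read_profile_dir <- function(dir, score_col = "aggregation") {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  out <- lapply(files, read_profile_file, score_col = score_col)
  names(out) <- sub("\\.tsv$", "", basename(files))
  out
}

#' Read an annotation table
#'
#' @param path TSV with columns `protein_id`, `keywords` (semicolon-joined),
#'   `chaperone_binder`, `disease_deposition`.
#' @return A `data.frame` with those columns.
#' @export
read_annotation_table <- function(path) {
  df <- read_tsv_checked(path,
                         c("protein_id", "keywords", "chaperone_binder",
                           "disease_deposition"))
  if (anyDuplicated(df$protein_id)) stop(path, ": duplicate protein ids")
  ok <- c("yes", "no", "unknown")
  if (!all(df$chaperone_binder %in% ok) || !all(df$disease_deposition %in% ok)) {
    stop(path, ": chaperone_binder/disease_deposition must be yes/no/unknown")
  }
  df
}

#' Read a normalized expression table
#'
#' @param path TSV with columns `protein_id`, `expression` (normalized,
#'   log scale).
#' @return Named numeric vector.
#' @export
read_expression_table <- function(path) {
  df <- read_tsv_checked(path, c("protein_id", "expression"))
  if (anyDuplicated(df$protein_id)) stop(path, ": duplicate protein ids")
  stats::setNames(as_numeric_checked(df$expression, "expression", path),
                  df$protein_id)
}

#' Read a per-segment thermodynamic-stability table
#'
#' Stability values are free-energy contributions of the segment in the native
#' structure (kcal/mol, lower = more stable), e.g. extracted from force-field
#' per-residue detail output; they are inputs here, never computed.
#'
#' @param path TSV with columns `protein_id`, `start`, `end` (1-based,
#'   inclusive) and `stability`.
#' @return A `data.frame` with numeric coordinates and stability.
#' @export
read_stability_table <- function(path) {
  df <- read_tsv_checked(path, c("protein_id", "start", "end", "stability"))
  out <- data.frame(
    protein_id = df$protein_id,
    start = as.integer(as_numeric_checked(df$start, "start", path)),
    end = as.integer(as_numeric_checked(df$end, "end", path)),
    stability = as_numeric_checked(df$stability, "stability", path),
    stringsAsFactors = FALSE
  )
  if (any(out$end < out$start)) stop(path, ": segment end before start")
  out
}

#' Remove trans-membrane and extracellular-matrix proteins
#'
#' Hydrophobic trans-membrane stretches are not under selective pressure
#' against aggregation, and extracellular proteins are degraded by lysosomes
#' rather than the proteasome, so both are excluded from turnover analyses.
#' The filter is purely keyword-based: records annotated `"KW-472"`
#' (Membrane) or `"KW-0272"` (Extracellular matrix) are removed.
#'
#' @param records protein-record `data.frame` with a `keywords` column.
#' @param exclude_keywords keyword codes that trigger removal.
#' @return `list(kept = ..., removed = ...)`, a partition of the input with
#'   row order preserved within each part.
#' @export
filter_membrane_extracellular <- function(records,
                                          exclude_keywords = c("KW-472", "KW-0272")) {
  kw <- strsplit(ifelse(is.na(records$keywords), "", records$keywords), ";",
                 fixed = TRUE)
  flagged <- vapply(kw, function(k) any(trimws(k) %in% exclude_keywords),
                    logical(1))
  list(kept = records[!flagged, , drop = FALSE],
       removed = records[flagged, , drop = FALSE])
}
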