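# Four-category PSI classification, the chaperone-binding enrichment
# statistic, and the deposition-disease category tally.

#' Ordered four-category PSI labels
#' @export
PSI_CATEGORIES <- c("short", "medium", "long", "extra_long")

#' Assign the four half-life categories from PSI
#'
#' Half-open intervals: short (PSI < 2), medium (2 <= PSI < 3), long
#' (3 <= PSI < 4) and extra-long (PSI >= 4). Note the deliberate asymmetry
#' with the two-group split, which uses PSI <= 2 for "short": both rules are
#' kept exactly as defined and never unified.
#'
#' @param psi numeric PSI vector in `[1, 7]` (`NA` allowed).
#' @return Ordered factor with levels [PSI_CATEGORIES].
#' @export
assign_four_category <- function(psi) {
  bad <- !is.na(psi) & (psi < 1 | psi > 7)
  if (any(bad)) stop("PSI outside [1, 7]")
  cut(psi, breaks = c(-Inf, 2, 3, 4, Inf), right = FALSE,
      labels = PSI_CATEGORIES, ordered_result = TRUE)
}

#' Per-category enrichment of a protein subset
#'
#' For a subset N of a total set T, partitioned into PSI categories c, the
#' enrichment in category c is
#' `e(c) = PSI_N(c) / PSI_T(c) - SUM_N / SUM_T`,
#' where `PSI_x(c)` counts set-x proteins in category c and `SUM_x` is the
#' size of set x. Positive `e(c)` means the subset is over-represented in
#' that category relative to its overall share. Categories with
#' `PSI_T(c) = 0` are reported with `NA` enrichment rather than dropped, so
#' tables keep a fixed shape. The counts satisfy the exact zero-sum identity
#' `sum_c PSI_T(c) * e(c) = 0` whenever N is a subset of T.
#'
#' @param psi_t integer vector of total-set counts per category.
#' @param psi_n integer vector of subset counts per category (same length).
#' @param categories category labels (default [PSI_CATEGORIES]).
#' @return `data.frame`: `category`, `PSI_T`, `PSI_N`, `e` (subset
#'   enrichment), `e_complement` (enrichment of T \ N).
#' @export
enrichment <- function(psi_t, psi_n, categories = PSI_CATEGORIES) {
  stopifnot(length(psi_t) == length(psi_n),
            length(categories) == length(psi_t))
  if (any(psi_t < 0) || any(psi_n < 0)) stop("negative category count")
  if (any(psi_n > psi_t)) {
    stop("PSI_N exceeds PSI_T in category: ",
         paste(categories[psi_n > psi_t], collapse = ", "))
  }
  sum_t <- sum(psi_t)
  sum_n <- sum(psi_n)
  if (sum_t == 0L) stop("empty total set")
  e <- ifelse(psi_t > 0, psi_n / psi_t - sum_n / sum_t, NA_real_)
  e_comp <- ifelse(psi_t > 0,
                   (psi_t - psi_n) / psi_t - (sum_t - sum_n) / sum_t,
                   NA_real_)
  data.frame(category = categories, PSI_T = as.integer(psi_t),
             PSI_N = as.integer(psi_n), e = e, e_complement = e_comp,
             stringsAsFactors = FALSE)
}

#' Chaperone-binding enrichment across PSI categories
#'
#' Builds the per-category counts from PSI values and chaperone-binder
#' labels, then applies [enrichment()] with N = the chaperone binders and
#' T = all proteins with both a PSI value and a known binder label.
#'
#' @param psi named numeric PSI vector (id -> PSI).
#' @param chaperone_binder named character vector (id -> yes/no/unknown) or a
#'   protein-record `data.frame` carrying `protein_id` and
#'   `chaperone_binder` columns.
#' @return `data.frame` as [enrichment()], with `e` the binder enrichment
#'   and `e_complement` the non-binder enrichment.
#' @export
chaperone_enrichment <- function(psi, chaperone_binder) {
  if (is.data.frame(chaperone_binder)) {
    chaperone_binder <- stats::setNames(chaperone_binder$chaperone_binder,
                                        chaperone_binder$protein_id)
  }
  ids <- intersect(names(psi)[!is.na(psi)],
                   names(chaperone_binder)[chaperone_binder %in% c("yes", "no")])
  if (length(ids) == 0L) stop("no proteins with both PSI and binder label")
  cat <- assign_four_category(unname(psi[ids]))
  binder <- chaperone_binder[ids] == "yes"
  psi_t <- as.integer(table(cat))
  psi_n <- as.integer(table(cat[binder]))
  enrichment(psi_t, psi_n)
}

#' Tally deposition-disease proteins per PSI category
#'
#' Counts proteins labelled as associated with a protein-deposition disease
#' in each of the four half-life categories, plus the combined short+medium
#' count (the fast-turnover side of the split).
#'
#' @param records protein-record `data.frame` with a `disease_deposition`
#'   column.
#' @param psi optional named PSI vector; defaults to the records' own `psi`
#'   column.
#' @return `list(table = <per-category counts>, total, short_medium)`.
#' @export
disease_category_tally <- function(records, psi = NULL) {
  if (is.null(psi)) {
    psi <- stats::setNames(records$psi, records$protein_id)
  }
  dis <- records$protein_id[records$disease_deposition == "yes"]
  vals <- unname(psi[dis])
  vals <- vals[!is.na(vals)]
  cat <- assign_four_category(vals)
  counts <- as.integer(table(cat))
  tab <- data.frame(category = PSI_CATEGORIES, n = counts,
                    stringsAsFactors = FALSE)
  list(table = tab, total = sum(counts),
       short_medium = sum(counts[PSI_CATEGORIES %in% c("short", "medium")]))
}
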