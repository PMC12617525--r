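# Elution-profile preprocessing: zero imputation, sparse-protein filtering,
# multi-engine averaging, and row/column normalization. The canonical stage
# order (impute -> filter -> combine -> normalize) is applied by
# preprocess_condition(); the individual steps are exported because each has
# its own contract.

#' Impute zeros for explicitly missing cells
#'
#' Missing proteins not detected by MS -- from low abundance or true absence
#' -- appear as missing cells; they are imputed as zero counts. Non-missing
#' cells are untouched.
#'
#' @param matrix an [elution_matrix()], possibly containing `NA` cells.
#' @return list with `matrix` (no missing cells) and `n_imputed_cells`.
#' @export
impute_zeros <- function(matrix) {
  miss <- is.na(unclass(matrix))
  matrix[miss] <- 0
  list(matrix = matrix, n_imputed_cells = sum(miss))
}

#' Remove proteins identified in at most one fraction
#'
#' A profile detected in a single fraction carries no co-elution information;
#' such proteins (and all-zero proteins) are excluded. Surviving rows are
#' returned unchanged (pure row deletion).
#'
#' @param matrix an [elution_matrix()] without missing cells.
#' @return list with `matrix`, `removed` (character vector of dropped ids),
#'   and a small report.
#' @export
filter_sparse <- function(matrix) {
  if (anyNA(matrix)) stop("run impute_zeros() before filter_sparse()")
  n_detected <- rowSums(unclass(matrix) > 0)
  keep <- n_detected > 1L
  list(matrix = matrix[keep, , drop = FALSE],
       removed = rownames(matrix)[!keep],
       report = list(n_input_proteins = nrow(matrix),
                     n_removed_single_fraction = sum(!keep)))
}

#' Row- and/or column-wise normalization of an elution matrix
#'
#' Row normalization rescales each protein profile to unit total, putting
#' proteins of different abundance on a common footing; column normalization
#' adjusts for fraction bias and injection discrepancies by rescaling each
#' fraction to unit total. `mode = "both"` applies the row pass and then the
#' column pass (fixed order). All-zero rows/columns are left unchanged, so
#' the zero pattern is preserved exactly and no NaN can arise.
#'
#' @param matrix an [elution_matrix()] without missing cells.
#' @param mode `"row"`, `"column"`, or `"both"`.
#' @return the normalized [elution_matrix()].
#' @export
normalize_profiles <- function(matrix, mode = c("row", "column", "both")) {
  mode <- match.arg(mode)
  if (anyNA(matrix)) stop("run impute_zeros() before normalize_profiles()")
  vals <- unclass(matrix)
  if (mode %in% c("row", "both")) {
    rs <- rowSums(vals)
    vals <- vals / ifelse(rs == 0, 1, rs)
  }
  if (mode %in% c("column", "both")) {
    cs <- colSums(vals)
    vals <- sweep(vals, 2L, ifelse(cs == 0, 1, cs), `/`)
  }
  elution_matrix(vals, attr(matrix, "genotype"), attr(matrix, "extract"),
                 attr(matrix, "engine"))
}

#' Average per-engine elution matrices into one analysis matrix
#'
#' Per-engine matrices for the same (genotype, extract) condition are aligned
#' on the union of their protein sets (a protein missed by one engine
#' contributes zero for that engine, preserving identification sensitivity)
#' and averaged cell-wise with the arithmetic mean. Fraction sets must agree.
#'
#' @param matrices list of [elution_matrix()] objects for one condition.
#' @return the combined [elution_matrix()] (engine label `"combined"`).
#' @export
combine_engines <- function(matrices) {
  if (!length(matrices)) stop("need at least one engine matrix")
  fracs <- lapply(matrices, colnames)
  if (length(unique(vapply(fracs, paste, character(1), collapse = "\t"))) != 1L)
    stop("conflicting fraction sets across engines")
  if (anyNA(unlist(lapply(matrices, unclass))))
    stop("run impute_zeros() before combine_engines()")
  proteins <- sort(unique(unlist(lapply(matrices, rownames))))
  acc <- matrix(0, length(proteins), ncol(matrices[[1L]]),
                dimnames = list(proteins, colnames(matrices[[1L]])))
  for (m in matrices) acc[rownames(m), ] <- acc[rownames(m), ] + unclass(m)
  elution_matrix(acc / length(matrices), attr(matrices[[1L]], "genotype"),
                 attr(matrices[[1L]], "extract"), engine = "combined")
}

#' Full preprocessing for one (genotype, extract) condition
#'
#' Applies the fixed stage order: impute zeros per engine, drop
#' single-fraction proteins per engine, optionally log2(x + 1) transform raw
#' intensities, average engines on the union of proteins, then normalize.
#'
#' @param matrices list of per-engine [elution_matrix()] objects.
#' @param mode normalization mode, see [normalize_profiles()].
#' @param log2_transform apply `log2(x + 1)` before averaging (for raw,
#'   untransformed intensities; spectral counts and already-log2 intensities
#'   should leave this `FALSE`).
#' @return list with `matrix` (the analysis matrix) and `report`
#'   (a preprocessing report: input/removed/imputed tallies and the modes
#'   used).
#' @export
preprocess_condition <- function(matrices, mode = "both", log2_transform = FALSE) {
  n_input <- length(unique(unlist(lapply(matrices, rownames))))
  n_imputed <- 0L
  removed <- character()
  cleaned <- lapply(matrices, function(m) {
    imp <- impute_zeros(m)
    n_imputed <<- n_imputed + imp$n_imputed_cells
    flt <- filter_sparse(imp$matrix)
    removed <<- union(removed, flt$removed)
    m <- flt$matrix
    if (log2_transform) m[] <- log2(unclass(m) + 1)
    m
  })
  combined <- combine_engines(cleaned)
  # proteins surviving in no engine are gone; ones surviving in >=1 remain
  removed <- setdiff(removed, rownames(combined))
  out <- normalize_profiles(combined, mode = mode)
  list(matrix = out,
       report = list(n_input_proteins = n_input,
                     n_removed_single_fraction = length(removed),
                     removed_proteins = sort(removed),
                     n_imputed_cells = n_imputed,
                     n_engines = length(matrices),
                     normalization_mode = mode,
                     log2_transform = log2_transform,
                     stage_order = c("impute", "filter_sparse",
                                     "combine_engines", "normalize")))
}
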