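# Cross-genotype differential analyses: exact-pattern network intersections,
# lost-interaction hub attribution, per-protein abundance-shift ranking, and
# complex-level gene-set enrichment (weighted Kolmogorov-Smirnov running sum
# with a gene-label permutation null).

#' Classify the union of several networks' edges by exact presence pattern
#'
#' Every edge of the union is assigned to exactly one subset cell -- the set
#' of genotypes whose network contains it -- so the cell counts sum to the
#' union edge count (the Venn decomposition of the networks).
#'
#' @param networks named list (genotype -> [scored_network()]) of >= 2
#'   networks from the same extract.
#' @return an `intersection_report` list: `genotypes`, `n_union`, `cells`
#'   (named counts, cell key = genotypes joined by `&`), and `edges` (named
#'   list of edge keys per cell).
#' @export
intersect_networks <- function(networks) {
  if (length(networks) < 2L) stop("need at least two networks")
  if (is.null(names(networks))) stop("networks must be named by genotype")
  extracts <- unique(vapply(networks, attr, "", "extract"))
  if (length(extracts) != 1L)
    stop("mixed extracts: ", paste(extracts, collapse = ", "))
  keys <- lapply(networks, edge_keys)
  union_keys <- sort(unique(unlist(keys)))
  present <- vapply(keys, function(k) union_keys %in% k,
                    logical(length(union_keys)))
  if (is.null(dim(present))) present <- matrix(present, nrow = 1L)
  pattern <- apply(present, 1L, function(row)
    paste(names(networks)[row], collapse = "&"))
  cells <- table(pattern)
  stopifnot(sum(cells) == length(union_keys))   # conservation invariant
  out <- list(genotypes = names(networks), extract = extracts,
              n_union = length(union_keys),
              cells = as.list(cells),
              edges = split(union_keys, pattern))
  class(out) <- "intersection_report"
  out
}

#' @export
print.intersection_report <- function(x, ...) {
  cat(sprintf("intersection_report: %d union edges across %s\n", x$n_union,
              paste(x$genotypes, collapse = ", ")))
  for (k in names(x$cells)) cat(sprintf("  %-30s %d\n", k, x$cells[[k]]))
  invisible(x)
}

#' Interactions present in a reference network and lost in all comparisons
#'
#' An interaction counts as lost when it is present (i.e. at or above
#' threshold) in the reference genotype's network and absent (below
#' threshold) from every comparison network. Each lost edge is attributed to
#' both of its endpoints, so the per-hub percentages over all involved
#' proteins sum to 200.
#'
#' @param reference the reference genotype's [scored_network()].
#' @param others list of comparison [scored_network()]s (same extract).
#' @return a `lost_ppi_report` list: `lost` (edge data.frame), `n_lost`,
#'   `involved_proteins`, and `hub_percent` (named percentage of lost edges
#'   incident to each involved protein, descending).
#' @export
lost_interactions <- function(reference, others) {
  if (!length(others)) stop("need at least one comparison network")
  extracts <- unique(c(attr(reference, "extract"),
                       vapply(others, attr, "", "extract")))
  if (length(extracts) != 1L)
    stop("mixed extracts: ", paste(extracts, collapse = ", "))
  other_keys <- unique(unlist(lapply(others, edge_keys)))
  lost <- as.data.frame(reference)[!edge_keys(reference) %in% other_keys, ,
                                   drop = FALSE]
  rownames(lost) <- NULL
  n_lost <- nrow(lost)
  involved <- sort(unique(c(lost$protein_a, lost$protein_b)))
  hub <- if (n_lost) {
    tab <- table(c(lost$protein_a, lost$protein_b))
    pct <- 100 * tab / n_lost
    pct <- pct[order(-pct, names(pct))]
    stats::setNames(as.vector(pct), names(pct))
  } else stats::setNames(numeric(0), character(0))
  out <- list(reference_genotype = attr(reference, "genotype"),
              comparison_genotypes = vapply(others, attr, "", "genotype"),
              extract = extracts, lost = lost, n_lost = n_lost,
              involved_proteins = involved, hub_percent = hub)
  class(out) <- "lost_ppi_report"
  out
}

#' @export
print.lost_ppi_report <- function(x, ...) {
  cat(sprintf("lost_ppi_report: %d PPIs of %s lost in {%s}, involving %d proteins\n",
              x$n_lost, x$reference_genotype,
              paste(x$comparison_genotypes, collapse = ", "),
              length(x$involved_proteins)))
  top <- utils::head(x$hub_percent, 5L)
  for (p in names(top)) cat(sprintf("  %-12s %.2f%%\n", p, top[[p]]))
  invisible(x)
}

#' Per-protein abundance-shift ranking statistic between two conditions
#'
#' For every protein of the union universe (absent proteins zero-filled), the
#' default statistic is the summed-abundance log-ratio
#' `log2((total_b + eps) / (total_a + eps))`; positive values mean higher
#' abundance in `matrix_b`. `mode = "per_fraction"` instead averages the
#' per-fraction log-ratios, weighting profile shape rather than totals.
#'
#' @param matrix_a,matrix_b [elution_matrix()] objects with equal fraction
#'   counts.
#' @param eps pseudo-abundance stabilizing the ratio (default 1).
#' @param mode `"total"` or `"per_fraction"`.
#' @return named numeric vector protein -> statistic (finite for every
#'   protein).
#' @export
rank_proteins <- function(matrix_a, matrix_b, eps = 1,
                          mode = c("total", "per_fraction")) {
  mode <- match.arg(mode)
  if (ncol(matrix_a) != ncol(matrix_b)) stop("fraction counts differ")
  proteins <- sort(unique(c(rownames(matrix_a), rownames(matrix_b))))
  align <- function(m) {
    out <- matrix(0, length(proteins), ncol(m),
                  dimnames = list(proteins, colnames(m)))
    out[rownames(m), ] <- unclass(m)
    out
  }
  A <- align(matrix_a); B <- align(matrix_b)
  stat <- if (mode == "total") {
    log2((rowSums(B) + eps) / (rowSums(A) + eps))
  } else {
    rowMeans(log2((B + eps) / (A + eps)))
  }
  stats::setNames(stat, proteins)
}

# weighted KS running-sum enrichment score from hit positions in a ranked
# (descending) statistic vector; O(set size) per evaluation
es_from_positions <- function(stats_sorted, hits, weight_exponent) {
  n <- length(stats_sorted); k <- length(hits)
  hits <- sort(hits)
  w <- abs(stats_sorted[hits])^weight_exponent
  if (sum(w) == 0) w <- rep(1, k)     # all-zero stats: fall back to unweighted
  cw <- cumsum(w) / sum(w)
  miss <- (hits - seq_len(k)) / (n - k)
  after <- cw - miss                  # running sum at each hit
  before <- c(0, cw[-k]) - miss       # running sum just before each hit
  hi <- max(after); lo <- min(before)
  if (hi >= -lo) {
    i <- which.max(after)
    list(es = hi, leading = hits[seq_len(i)])
  } else {
    i <- which.min(before)
    list(es = lo, leading = hits[seq(i, k)])
  }
}

#' Complex-level gene-set enrichment on a co-elution ranking
#'
#' Treats each complex as a gene set and scores it against a per-protein
#' ranking statistic (e.g. from [rank_proteins()]) with the weighted
#' Kolmogorov-Smirnov running-sum enrichment score: walking down the ranked
#' list, the running sum rises by the (|statistic|^`weight_exponent`)
#' -normalized weight at members and falls by 1/(N - k) at non-members; ES is
#' the extremum. The null is gene-label permutation (random same-size member
#' sets), the normalized ES divides by the mean of same-sign null scores, and
#' p-values are BH-adjusted across complexes.
#'
#' @param ranking named numeric vector protein -> ranking statistic.
#' @param complexes a [complex_catalog()]; complexes with fewer than 3
#'   members in the ranking universe are skipped (and logged in the result).
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param weight_exponent KS weight exponent (1 = classic weighted; 0 =
#'   unweighted KS statistic).
#' @param seed RNG seed for the permutation null.
#' @return an `enrichment_result` data.frame: `complex_id`, `size`, `es`,
#'   `nes`, `p`, `q`, `direction`, `leading_edge` (";"-joined members);
#'   skipped complexes (fewer than 3 ranked members, or no non-member left
#'   to contrast against) in `attr(, "skipped")`.
#' @export
complex_gsea <- function(ranking, complexes, n_perm = 1000L,
                         weight_exponent = 1, seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  ord <- order(ranking, decreasing = TRUE)
  stats_sorted <- as.numeric(ranking[ord])
  universe <- names(ranking)[ord]
  n <- length(universe)
  sets <- lapply(complexes, intersect, y = universe)
  # a set needs >= 3 ranked members and at least one non-member to contrast
  usable <- lengths(sets) >= 3L & lengths(sets) < n
  skipped <- names(complexes)[!usable]
  sets <- sets[usable]
  rows <- local_seed(seed, lapply(names(sets), function(id) {
    members <- sets[[id]]
    k <- length(members)
    obs <- es_from_positions(stats_sorted, match(members, universe),
                             weight_exponent)
    null <- vapply(seq_len(n_perm), function(i)
      es_from_positions(stats_sorted, sample.int(n, k), weight_exponent)$es,
      numeric(1))
    same <- null[sign(null) == sign(obs$es) | null == 0]
    p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
    nes <- if (length(same) && mean(abs(same)) > 0)
      obs$es / mean(abs(same)) else NA_real_
    data.frame(complex_id = id, size = k, es = obs$es, nes = nes, p = p,
               direction = if (obs$es >= 0) "up" else "down",
               leading_edge = paste(universe[sort(obs$leading)],
                                    collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(complex_id = character(), size = integer(), es = numeric(),
               nes = numeric(), p = numeric(), direction = character(),
               leading_edge = character(), stringsAsFactors = FALSE)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[c("complex_id", "size", "es", "nes", "p", "q", "direction",
               "leading_edge")]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"),
            skipped = skipped, n_perm = as.integer(n_perm),
            weight_exponent = weight_exponent, seed = as.integer(seed))
}

#' Protein sets exclusive to one genotype's predicted complexes
#'
#' Complexes predicted in one genotype whose member set matches (at
#' `omega >= omega_min`) no complex of any other genotype; the exported sets
#' feed downstream annotation enrichment.
#'
#' @param catalogs named list (genotype -> predicted [complex_catalog()]).
#' @param omega_min overlap criterion treating two complexes as the same
#'   assembly (default 0.25).
#' @return named list genotype -> [complex_catalog()] of exclusive complexes.
#' @export
exclusive_assemblies <- function(catalogs, omega_min = 0.25) {
  lapply(stats::setNames(names(catalogs), names(catalogs)), function(g) {
    own <- catalogs[[g]]
    other <- unlist(catalogs[setdiff(names(catalogs), g)], recursive = FALSE)
    keep <- Filter(function(m)
      !length(other) || all(vapply(other, overlap_score, numeric(1), a = m) <
                              omega_min), own)
    complex_catalog(keep, source = "predicted")
  })
}
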