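# Co-elution similarity features. Each registered metric maps two equal-length
# non-negative elution profiles to a scalar similarity; the engine computes
# whole protein x protein metric matrices at once so that all-vs-all feature
# tables stay fast, and extracts the requested pairs.
#
# Degenerate-profile rule: a zero-variance (e.g. all-zero) profile makes
# correlation-type metrics undefined; they return 0 for such pairs. The rule
# keeps the feature table total, and such pairs carry no co-elution signal.

map_nonfinite <- function(S, value = 0) { S[!is.finite(S)] <- value; S }

sim_cor <- function(method) function(X) {
  map_nonfinite(suppressWarnings(stats::cor(t(X), method = method)))
}

sim_cosine <- function(X) {
  n <- sqrt(rowSums(X^2))
  map_nonfinite(tcrossprod(X) / outer(n, n))
}

sim_euclidean <- function(X) 1 / (1 + as.matrix(stats::dist(X)))

sim_manhattan <- function(X) 1 / (1 + as.matrix(stats::dist(X, method = "manhattan")))

sim_bray <- function(X) {
  S <- 1 - as.matrix(suppressWarnings(vegan::vegdist(X, method = "bray")))
  map_nonfinite(S)
}

binary_counts <- function(X) {
  B <- (X > 0) * 1
  list(inter = tcrossprod(B), n = rowSums(B))
}

sim_jaccard <- function(X) {
  bc <- binary_counts(X)
  un <- outer(bc$n, bc$n, `+`) - bc$inter
  map_nonfinite(bc$inter / un)
}

sim_dice <- function(X) {
  bc <- binary_counts(X)
  map_nonfinite(2 * bc$inter / outer(bc$n, bc$n, `+`))
}

sim_apex <- function(X) {
  apex <- max.col(X, ties.method = "first")
  S <- 1 / (1 + abs(outer(apex, apex, `-`)))
  deg <- apply(X, 1L, function(v) max(v) == min(v))
  S[deg, ] <- 0; S[, deg] <- 0
  S
}

sim_xcor_max <- function(X, max_shift = 2L) {
  nf <- ncol(X)
  best <- sim_cor("pearson")(X)
  for (s in seq_len(min(max_shift, nf - 2L))) {
    Cs <- map_nonfinite(suppressWarnings(
      stats::cor(t(X[, seq_len(nf - s), drop = FALSE]),
                 t(X[, (1L + s):nf, drop = FALSE]))))
    best <- pmax(best, Cs, t(Cs))
  }
  deg <- apply(X, 1L, function(v) max(v) == min(v))
  best[deg, ] <- 0; best[, deg] <- 0
  best
}

sim_mutual_information <- function(X, n_bins = 5L) {
  nf <- ncol(X)
  rng_min <- apply(X, 1L, min); rng_max <- apply(X, 1L, max)
  width <- (rng_max - rng_min) / n_bins
  width[width == 0] <- 1          # constant profile -> all mass in bin 1 -> MI 0
  bin <- pmin(floor((X - rng_min) / width) + 1L, n_bins)
  ind <- lapply(seq_len(n_bins), function(b) (bin == b) * 1)
  marg <- lapply(ind, rowSums)
  mi <- matrix(0, nrow(X), nrow(X), dimnames = list(rownames(X), rownames(X)))
  for (b in seq_len(n_bins)) for (cc in seq_len(n_bins)) {
    J <- ind[[b]] %*% t(ind[[cc]])
    M <- outer(marg[[b]], marg[[cc]])
    term <- J / nf * log2(pmax(J, 1) * nf / pmax(M, 1))
    term[J == 0] <- 0
    mi <- mi + term
  }
  pmin(pmax(mi / log2(n_bins), 0), 1)   # scaled to [0, 1]
}

sim_co_peak <- function(X, quantile = 0.75) {
  thr <- apply(X, 1L, stats::quantile, probs = quantile, names = FALSE)
  B <- (X > thr) * 1
  np <- rowSums(B)
  map_nonfinite(tcrossprod(B) / outer(np, np, pmin))
}

# registry: name -> list(matrix_fun, family). "correlation" metrics are
# invariant to positive rescaling of one profile; "abundance" metrics are not.
metric_registry <- function() list(
  pearson                = list(fun = sim_cor("pearson"),  family = "correlation"),
  spearman               = list(fun = sim_cor("spearman"), family = "correlation"),
  kendall                = list(fun = sim_cor("kendall"),  family = "correlation"),
  cosine                 = list(fun = sim_cosine,          family = "correlation"),
  dice                   = list(fun = sim_dice,            family = "detection"),
  jaccard_codetection    = list(fun = sim_jaccard,         family = "detection"),
  bray_curtis_similarity = list(fun = sim_bray,            family = "abundance"),
  euclidean_similarity   = list(fun = sim_euclidean,       family = "abundance"),
  manhattan_similarity   = list(fun = sim_manhattan,       family = "abundance"),
  apex_match             = list(fun = sim_apex,            family = "shape"),
  cross_correlation_max  = list(fun = sim_xcor_max,        family = "correlation"),
  mutual_information     = list(fun = sim_mutual_information, family = "shape"),
  co_peak_count          = list(fun = sim_co_peak,         family = "shape")
)

#' Names of the registered co-elution similarity metrics
#'
#' The default registry provides 13 named metrics spanning correlation
#' (pearson, spearman, kendall, cosine, cross_correlation_max), co-detection
#' (jaccard_codetection, dice), abundance distance (bray_curtis_similarity,
#' euclidean_similarity with similarity 1/(1+d), manhattan_similarity), and
#' peak-shape (apex_match, mutual_information, co_peak_count) families. The
#' set is extensible and classifiers accept any registered subset.
#'
#' @return character vector of metric names.
#' @export
similarity_metrics <- function() names(metric_registry())

#' A single similarity metric as a pairwise function
#'
#' @param name a registered metric name, see [similarity_metrics()].
#' @return function(profile_a, profile_b) -> scalar similarity. Rejects
#'   length-mismatched profiles.
#' @examples
#' similarity_metric("apex_match")(c(0, 1, 0, 0), c(0, 0, 0, 1))
#' @export
similarity_metric <- function(name) {
  reg <- metric_registry()
  if (!name %in% names(reg))
    stop("unknown metric '", name, "'; valid: ",
         paste(names(reg), collapse = ", "))
  fun <- reg[[name]]$fun
  function(profile_a, profile_b) {
    if (length(profile_a) != length(profile_b))
      stop("profile length mismatch (", length(profile_a), " vs ",
           length(profile_b), ")")
    X <- rbind(a = as.numeric(profile_a), b = as.numeric(profile_b))
    unname(fun(X)[1L, 2L])
  }
}

#' Compute the per-pair co-elution similarity feature table
#'
#' For every candidate protein pair of a preprocessed elution matrix, every
#' requested metric is evaluated on the two profile vectors. The default
#' candidate policy is all-vs-all among the matrix's proteins; an explicit
#' pair list restricts computation, and `prefilter_floor` optionally drops
#' pairs whose best correlation-family metric is below a floor.
#'
#' @param matrix a preprocessed [elution_matrix()].
#' @param metrics metric names from [similarity_metrics()] (default: all).
#' @param pairs optional data.frame with `protein_a`, `protein_b` columns
#'   restricting the candidate pairs (unknown proteins rejected).
#' @param prefilter_floor optional numeric; with the all-vs-all policy, keep
#'   only pairs with some correlation-family metric >= the floor.
#' @return a `pair_features` data.frame: `protein_a`, `protein_b` (canonical
#'   order) plus one numeric column per metric; never any NA.
#' @export
compute_features <- function(matrix, metrics = similarity_metrics(),
                             pairs = NULL, prefilter_floor = NULL) {
  reg <- metric_registry()
  bad <- setdiff(metrics, names(reg))
  if (length(bad))
    stop("unknown metric(s): ", paste(bad, collapse = ", "),
         "; valid: ", paste(names(reg), collapse = ", "))
  if (!length(metrics)) stop("metric set must be non-empty")
  if (anyNA(matrix)) stop("feature computation requires an imputed matrix")
  if (!is.null(pairs)) {
    a <- as.character(pairs$protein_a); b <- as.character(pairs$protein_b)
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    unknown <- setdiff(unique(c(a, b)), rownames(matrix))
    if (length(unknown))
      stop("pair protein(s) absent from matrix: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
    proteins <- sort(unique(c(a, b)))
  } else {
    proteins <- rownames(matrix)
    if (length(proteins) < 2L) stop("need at least two proteins")
    idx <- utils::combn(seq_along(proteins), 2L)
    a <- proteins[idx[1L, ]]; b <- proteins[idx[2L, ]]
  }
  X <- unclass(matrix)[proteins, , drop = FALSE]
  ia <- match(a, proteins); ib <- match(b, proteins)
  feat <- matrix(0, length(a), length(metrics),
                 dimnames = list(NULL, metrics))
  for (m in metrics) {
    S <- reg[[m]]$fun(X)
    feat[, m] <- S[cbind(ia, ib)]
  }
  stopifnot(!anyNA(feat))
  out <- data.frame(protein_a = a, protein_b = b, feat,
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- out[order(out$protein_a, out$protein_b), , drop = FALSE]
  out <- out[!duplicated(paste(out$protein_a, out$protein_b)), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(prefilter_floor)) {
    corr <- intersect(metrics,
                      names(Filter(function(e) e$family == "correlation", reg)))
    if (length(corr)) {
      best <- do.call(pmax, out[corr])
      out <- out[best >= prefilter_floor, , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  structure(out, class = c("pair_features", "data.frame"),
            metrics = metrics,
            genotype = attr(matrix, "genotype"),
            extract = attr(matrix, "extract"))
}
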