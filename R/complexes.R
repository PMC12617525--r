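# Overlapping complex detection on a scored PPI network: greedy cohesiveness
# growth from high-degree seeds, transitive merging of highly overlapping
# candidates, density/size filtering, and composite-score (Acc + MMR +
# Overlap) model selection over a (density, overlap) parameter grid.

# dense symmetric weight matrix of a scored network
network_weights <- function(network) {
  prot <- network_proteins(network)
  W <- matrix(0, length(prot), length(prot), dimnames = list(prot, prot))
  ia <- match(network$protein_a, prot); ib <- match(network$protein_b, prot)
  W[cbind(ia, ib)] <- network$score
  W[cbind(ib, ia)] <- network$score
  W
}

cohesiveness_w <- function(W, members, penalty) {
  inside <- rownames(W) %in% members
  w_in <- sum(W[inside, inside, drop = FALSE]) / 2
  w_bound <- sum(W[inside, !inside, drop = FALSE])
  den <- w_in + w_bound + penalty * sum(inside)
  if (den == 0) 0 else w_in / den
}

#' Cohesiveness of a node set in a weighted network
#'
#' The clustering objective: `w_in / (w_in + w_bound + penalty * |V|)` where
#' `w_in` is the total internal edge weight of the set, `w_bound` the total
#' weight of edges crossing its boundary, and the penalty term models unseen
#' connections of each member. Equals 1 exactly when the set has internal
#' weight, no boundary weight, and zero penalty.
#'
#' @param network a [scored_network()].
#' @param node_set non-empty character vector of member proteins.
#' @param penalty non-negative per-node boundary penalty (default 2).
#' @return scalar in [0, 1].
#' @examples
#' tri <- scored_network(data.frame(protein_a = c("A", "A", "B"),
#'                                  protein_b = c("B", "C", "C"), score = 1))
#' cohesiveness(tri, c("A", "B", "C"), penalty = 0)  # 1
#' @export
cohesiveness <- function(network, node_set, penalty = 2) {
  node_set <- unique(as.character(node_set))
  if (!length(node_set)) stop("node set must be non-empty")
  unknown <- setdiff(node_set, network_proteins(network))
  if (length(unknown))
    stop("node(s) not in network: ", paste(unknown, collapse = ", "))
  cohesiveness_w(network_weights(network), node_set, penalty)
}

#' Overlap score between two protein sets
#'
#' `omega(A, B) = |A intersect B|^2 / (|A| * |B|)`; the match criterion
#' between predicted and reference complexes (conventional match at
#' `omega >= 0.25`).
#'
#' @param a,b character vectors.
#' @return scalar in [0, 1].
#' @export
overlap_score <- function(a, b) {
  a <- unique(a); b <- unique(b)
  length(intersect(a, b))^2 / (length(a) * length(b))
}

# grow one candidate from a seed: best single-node addition or removal while
# cohesiveness strictly improves -> locally optimal under single-node moves
grow_candidate <- function(W, seed, penalty) {
  n <- nrow(W)
  inside <- logical(n); inside[seed] <- TRUE
  w_in <- 0
  w_bound <- sum(W[seed, ])
  coh <- function(wi, wb, size) {
    den <- wi + wb + penalty * size
    ifelse(den == 0, 0, wi / den)
  }
  current <- coh(w_in, w_bound, 1L)
  repeat {
    size <- sum(inside)
    in_w <- if (size) rowSums(W[, inside, drop = FALSE]) else numeric(n)
    out_w <- rowSums(W) - in_w
    # additions: any outside node with a connection to the cluster
    cand_add <- which(!inside & in_w > 0)
    gain_add <- coh(w_in + in_w[cand_add], w_bound - in_w[cand_add] +
                      out_w[cand_add], size + 1L)
    # removals: keep the set non-empty
    cand_rem <- if (size > 1L) which(inside) else integer()
    gain_rem <- coh(w_in - in_w[cand_rem], w_bound + in_w[cand_rem] -
                      out_w[cand_rem], size - 1L)
    moves <- c(gain_add, gain_rem)
    if (!length(moves) || max(moves) <= current) break
    best <- which.max(moves)
    if (best <= length(cand_add)) {
      v <- cand_add[best]
      w_in <- w_in + in_w[v]; w_bound <- w_bound - in_w[v] + out_w[v]
      inside[v] <- TRUE
    } else {
      v <- cand_rem[best - length(cand_add)]
      w_in <- w_in - in_w[v]; w_bound <- w_bound + in_w[v] - out_w[v]
      inside[v] <- FALSE
    }
    current <- max(moves)
  }
  which(inside)
}

# merge candidate sets whose pairwise overlap exceeds `o`, transitively,
# iterated to a fixpoint so the pass is idempotent
merge_candidates <- function(sets, o) {
  repeat {
    sets <- unique(lapply(sets, sort))
    n <- length(sets)
    if (n < 2L) return(sets)
    ov <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      ov[i, j] <- ov[j, i] <- overlap_score(sets[[i]], sets[[j]])
    if (all(ov <= o)) return(sets)
    g <- igraph::graph_from_adjacency_matrix(ov > o, mode = "undirected")
    comp <- igraph::components(g)$membership
    sets <- lapply(split(seq_len(n), comp),
                   function(i) sort(unique(unlist(sets[i]))))
  }
}

internal_density <- function(W, members) {
  k <- length(members)
  if (k < 2L) return(0)
  sum(W[members, members]) / 2 / (k * (k - 1) / 2)
}

#' Detect overlapping complexes by greedy cohesiveness clustering
#'
#' Candidates are grown greedily from unused seed nodes taken in descending
#' weighted-degree order, adding or removing one node at a time while the
#' [cohesiveness()] strictly improves (so each candidate is locally optimal
#' under single-node moves). Candidate pairs with overlap
#' `omega > o` are then merged transitively (iterated to a fixpoint, so the
#' merge pass is idempotent; note merged unions are consolidations and need
#' not themselves be locally optimal), and finally groups below `min_size`
#' or with internal weighted density below `d` are discarded. Surviving
#' complexes may share members.
#'
#' @param network a [scored_network()].
#' @param d minimum internal density (sum of internal edge weights over
#'   possible pairs), conventional sweep range 0.2-0.45.
#' @param o merge-overlap threshold, conventional sweep range 0.5-0.8
#'   (`o = 1` disables merging).
#' @param penalty per-node boundary penalty (default 2).
#' @param min_size smallest reported complex (default 3).
#' @return a predicted [complex_catalog()] (ids `K001`, `K002`, ... in order
#'   of decreasing size).
#' @export
detect_complexes <- function(network, d = 0.3, o = 0.8, penalty = 2,
                             min_size = 3L) {
  if (!nrow(network)) return(complex_catalog(list(), source = "predicted"))
  W <- network_weights(network)
  finalize_candidates(grow_all_candidates(W, penalty), W, d, o, min_size)
}

# greedy growth from every unused seed, in descending weighted-degree order
grow_all_candidates <- function(W, penalty) {
  prot <- rownames(W)
  used <- logical(length(prot))
  order_seed <- order(-rowSums(W), prot)   # weighted degree, ties by name
  cands <- list()
  for (s in order_seed) {
    if (used[s]) next
    members <- grow_candidate(W, s, penalty)
    used[members] <- TRUE
    cands[[length(cands) + 1L]] <- prot[members]
  }
  cands
}

# merge pass, then density/size filters (fixed discard order)
finalize_candidates <- function(cands, W, d, o, min_size) {
  merged <- merge_candidates(cands, o)
  keep <- Filter(function(m) length(m) >= min_size &&
                   internal_density(W, m) >= d, merged)
  keep <- keep[order(-lengths(keep), vapply(keep, `[[`, character(1), 1L))]
  if (!length(keep)) return(complex_catalog(list(), source = "predicted"))
  names(keep) <- sprintf("K%03d", seq_along(keep))
  complex_catalog(keep, source = "predicted")
}

#' Match predicted against reference complexes
#'
#' Computes the standard complex-prediction metrics: clustering-wise
#' sensitivity Sn and positive predictive value PPV from the reference x
#' prediction member-overlap confusion matrix, their geometric mean
#' `Acc = sqrt(Sn * PPV)`; the maximum matching ratio `MMR` (weight of the
#' maximum one-to-one bipartite matching under the [overlap_score()] omega,
#' divided by the number of reference complexes); `Overlap`, the fraction of
#' reference complexes attaining `omega >= omega_min` with some prediction;
#' and the composite score `Acc + Overlap + MMR` used for parameter
#' selection.
#'
#' @param predicted,reference non-empty [complex_catalog()] objects.
#' @param omega_min match criterion for the Overlap component (default 0.25).
#' @return a `match_report` list with components `sn`, `ppv`, `acc`, `mmr`,
#'   `overlap`, `composite`, and `matched_reference` (logical per reference
#'   complex).
#' @export
match_metrics <- function(predicted, reference, omega_min = 0.25) {
  if (!length(predicted) || !length(reference))
    stop("both catalogs must be non-empty")
  nr <- length(reference); np <- length(predicted)
  Tm <- matrix(0L, nr, np, dimnames = list(names(reference), names(predicted)))
  Om <- matrix(0, nr, np)
  for (i in seq_len(nr)) for (j in seq_len(np)) {
    Tm[i, j] <- length(intersect(reference[[i]], predicted[[j]]))
    Om[i, j] <- overlap_score(reference[[i]], predicted[[j]])
  }
  sn <- sum(apply(Tm, 1L, max)) / sum(lengths(reference))
  denom_ppv <- sum(Tm)
  ppv <- if (denom_ppv == 0) 0 else sum(apply(Tm, 2L, max)) / denom_ppv
  acc <- sqrt(sn * ppv)
  mmr <- max_matching_weight(Om) / nr
  matched <- apply(Om, 1L, max) >= omega_min
  rep <- list(sn = sn, ppv = ppv, acc = acc, mmr = mmr,
              overlap = mean(matched),
              composite = acc + mean(matched) + mmr,
              matched_reference = matched)
  class(rep) <- "match_report"
  rep
}

# maximum-weight one-to-one bipartite matching on an omega matrix
max_matching_weight <- function(Om) {
  pos <- which(Om > 0, arr.ind = TRUE)
  if (!nrow(pos)) return(0)
  nr <- nrow(Om); np <- ncol(Om)
  g <- igraph::make_bipartite_graph(
    types = rep(c(FALSE, TRUE), c(nr, np)),
    edges = as.vector(t(cbind(pos[, 1L], nr + pos[, 2L]))))
  m <- igraph::max_bipartite_match(g, weights = Om[pos])
  sum(m$matching_weight)
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("match_report: Sn=%.3f PPV=%.3f Acc=%.3f MMR=%.3f Overlap=%.3f composite=%.3f\n",
              x$sn, x$ppv, x$acc, x$mmr, x$overlap, x$composite))
  invisible(x)
}

#' Composite-score optimization over the (density, overlap) grid
#'
#' Runs [detect_complexes()] at every grid cell, evaluates each prediction
#' against the reference with [match_metrics()], and returns the parameters
#' with the highest composite score (Acc + Overlap + MMR). Ties are broken
#' toward higher density, then higher overlap.
#'
#' @param network a [scored_network()].
#' @param reference a reference [complex_catalog()].
#' @param d_grid,o_grid numeric grids (conventional ranges 0.2-0.45 and
#'   0.5-0.8).
#' @param penalty,min_size passed to [detect_complexes()].
#' @return list with `best` (d, o, the catalog, and its match report) and
#'   `grid` (data.frame of every cell's metrics).
#' @export
optimize_params <- function(network, reference,
                            d_grid = seq(0.2, 0.45, by = 0.05),
                            o_grid = seq(0.5, 0.8, by = 0.1),
                            penalty = 2, min_size = 3L) {
  if (!length(d_grid) || !length(o_grid)) stop("grids must be non-empty")
  cells <- expand.grid(d = d_grid, o = o_grid)
  W <- if (nrow(network)) network_weights(network) else NULL
  cands <- if (nrow(network)) grow_all_candidates(W, penalty) else list()
  res <- lapply(seq_len(nrow(cells)), function(i) {
    cat_i <- if (is.null(W)) complex_catalog(list(), source = "predicted") else
      finalize_candidates(cands, W, cells$d[i], cells$o[i], min_size)
    if (!length(cat_i))
      return(list(catalog = cat_i,
                  rep = list(sn = 0, ppv = 0, acc = 0, mmr = 0, overlap = 0,
                             composite = 0)))
    list(catalog = cat_i, rep = match_metrics(cat_i, reference))
  })
  grid <- cbind(cells, do.call(rbind, lapply(res, function(r)
    data.frame(n_complexes = length(r$catalog), acc = r$rep$acc,
               mmr = r$rep$mmr, overlap = r$rep$overlap,
               composite = r$rep$composite))))
  best_comp <- max(grid$composite)
  tied <- which(grid$composite == best_comp)
  tied <- tied[order(-grid$d[tied], -grid$o[tied])]
  b <- tied[1L]
  list(best = list(d = grid$d[b], o = grid$o[b], penalty = penalty,
                   min_size = min_size, catalog = res[[b]]$catalog,
                   report = res[[b]]$rep),
       grid = grid)
}
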