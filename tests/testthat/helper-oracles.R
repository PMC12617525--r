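# Independent brute-force oracles and tiny fixture builders. Everything here
# is deliberately naive (double loops, exhaustive enumeration) and shares no
# code with the vectorized implementations it checks.

toy_matrix <- function(values, proteins = NULL, ...) {
  m <- matrix(values, nrow = if (is.null(proteins)) 2 else length(proteins),
              byrow = TRUE)
  rownames(m) <- if (is.null(proteins)) c("A", "B") else proteins
  elution_matrix(m, ...)
}

random_elution <- function(n_proteins, n_fractions, seed) {
  withr::with_seed(seed, {
    m <- matrix(stats::rpois(n_proteins * n_fractions, 4),
                n_proteins, n_fractions,
                dimnames = list(sprintf("P%02d", seq_len(n_proteins)), NULL))
    m[stats::runif(length(m)) < 0.2] <- 0
    elution_matrix(m * 1.0)
  })
}

# per-pair similarity oracles (naive formulas, no vectorization)
oracle_metric <- function(name, a, b) {
  a <- unname(a); b <- unname(b)
  safe <- function(x) if (!is.finite(x)) 0 else x
  switch(name,
    pearson  = safe(suppressWarnings(cor(a, b))),
    spearman = safe(suppressWarnings(cor(a, b, method = "spearman"))),
    kendall  = safe(suppressWarnings(cor(a, b, method = "kendall"))),
    cosine   = safe(sum(a * b) / sqrt(sum(a^2) * sum(b^2))),
    euclidean_similarity = 1 / (1 + sqrt(sum((a - b)^2))),
    manhattan_similarity = 1 / (1 + sum(abs(a - b))),
    bray_curtis_similarity = safe(1 - sum(abs(a - b)) / sum(a + b)),
    jaccard_codetection = {
      u <- sum(a > 0 | b > 0)
      if (u == 0) 0 else sum(a > 0 & b > 0) / u
    },
    dice = {
      s <- sum(a > 0) + sum(b > 0)
      if (s == 0) 0 else 2 * sum(a > 0 & b > 0) / s
    },
    apex_match = {
      if (max(a) == min(a) || max(b) == min(b)) 0 else
        1 / (1 + abs(which.max(a) - which.max(b)))
    },
    cross_correlation_max = {
      if (max(a) == min(a) || max(b) == min(b)) return(0)
      n <- length(a)
      best <- -Inf
      for (s in -2:2) {
        ia <- seq_len(n - abs(s))
        x <- if (s >= 0) a[ia] else a[ia + abs(s)]
        y <- if (s >= 0) b[ia + s] else b[ia]
        r <- suppressWarnings(cor(x, y))
        if (is.finite(r)) best <- max(best, r)
      }
      if (is.finite(best)) best else 0
    },
    mutual_information = {
      bin <- function(v) {
        if (max(v) == min(v)) return(rep(1L, length(v)))
        w <- (max(v) - min(v)) / 5
        pmin(floor((v - min(v)) / w) + 1L, 5L)
      }
      ja <- bin(a); jb <- bin(b); n <- length(a)
      mi <- 0
      for (x in 1:5) for (y in 1:5) {
        pxy <- sum(ja == x & jb == y) / n
        if (pxy > 0)
          mi <- mi + pxy * log2(pxy / (sum(ja == x) / n * sum(jb == y) / n))
      }
      min(max(mi / log2(5), 0), 1)
    },
    co_peak_count = {
      pa <- a > quantile(a, 0.75); pb <- b > quantile(b, 0.75)
      d <- min(sum(pa), sum(pb))
      if (d == 0) 0 else sum(pa & pb) / d
    },
    stop("no oracle for ", name))
}

# direct cohesiveness from the edge list (no weight matrix)
oracle_cohesiveness <- function(network, members, penalty) {
  a_in <- network$protein_a %in% members
  b_in <- network$protein_b %in% members
  w_in <- sum(network$score[a_in & b_in])
  w_bound <- sum(network$score[xor(a_in, b_in)])
  den <- w_in + w_bound + penalty * length(members)
  if (den == 0) 0 else w_in / den
}

# exhaustive maximum-weight one-to-one matching over an omega matrix
oracle_matching <- function(Om) {
  nr <- nrow(Om); np <- ncol(Om)
  if (nr <= np) {
    perms <- all_injections(nr, np)
    best <- 0
    for (p in perms) best <- max(best, sum(Om[cbind(seq_len(nr), p)]))
  } else {
    perms <- all_injections(np, nr)
    best <- 0
    for (p in perms) best <- max(best, sum(Om[cbind(p, seq_len(np))]))
  }
  best
}

all_injections <- function(k, n) {
  if (k == 0) return(list(integer()))
  out <- list()
  rec <- function(prefix, remaining) {
    if (length(prefix) == k) { out[[length(out) + 1L]] <<- prefix; return() }
    for (v in remaining) rec(c(prefix, v), setdiff(remaining, v))
  }
  rec(integer(), seq_len(n))
  out
}

# direct O(N) running-sum KS enrichment score over a full ranked list
oracle_es <- function(ranking, set, weight_exponent = 0) {
  ord <- order(ranking, decreasing = TRUE)
  ranked <- names(ranking)[ord]
  stats <- ranking[ord]
  hit <- ranked %in% set
  w <- abs(stats)^weight_exponent
  w[!hit] <- 0
  if (sum(w) == 0) w[hit] <- 1
  run <- cumsum(ifelse(hit, w / sum(w), -1 / sum(!hit)))
  run[which.max(abs(run))]
}

# random small weighted graph as a scored_network
random_graph <- function(n, p = 0.4, seed = 1) {
  withr::with_seed(seed, {
    prot <- sprintf("N%02d", seq_len(n))
    idx <- utils::combn(n, 2)
    keep <- stats::runif(ncol(idx)) < p
    if (!any(keep)) keep[1] <- TRUE
    scored_network(data.frame(protein_a = prot[idx[1, keep]],
                              protein_b = prot[idx[2, keep]],
                              score = round(stats::runif(sum(keep), 0.1, 1), 3)))
  })
}
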