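# Synthetic ground truth: planted complexes with genotype-specific rewiring,
# SEC-like co-elution matrices with count noise and dropout, and spot-level
# negative-binomial counts with planted DEGs. Everything downstream of the
# instrument is testable against these generators.

#' Simulation configuration for the CF-MS arm
#'
#' Defaults emulate the study design this pipeline targets: 96 SEC fractions,
#' 50 planted complexes of 3-8 subunits, a background of monomeric proteins,
#' three search-engine replicates, and moderate count noise/dropout (chosen
#' once so that ensemble cross-validation lands in a realistic 0.8-0.95
#' auROC band).
#'
#' @param n_complexes number of planted complexes.
#' @param complex_size_range (min, max) subunits per complex; min >= 3.
#' @param n_background_proteins proteins outside any complex.
#' @param n_fractions SEC fractions (default 96; >= 4).
#' @param peak_width_range (min, max) Gaussian peak SD, in fractions.
#' @param apex_jitter maximum per-member apex offset, in fractions (<= 1).
#' @param abundance_scale median peak amplitude, arbitrary count units.
#' @param count_noise extra overdispersion of the count draw (gamma-Poisson
#'   mixing variance; 0 disables count sampling entirely, yielding
#'   noise-free continuous profiles).
#' @param dropout_prob probability a (protein, fraction, engine) cell is
#'   zeroed; in [0, 1).
#' @param n_engines independent noisy search-engine replicates.
#' @param n_proteins optional cap on the protein pool; rejected if the
#'   complex sizes cannot fit.
#' @param seed master RNG seed for the generators.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_complexes = 50L, complex_size_range = c(3L, 8L),
                       n_background_proteins = 150L, n_fractions = 96L,
                       peak_width_range = c(5, 12), apex_jitter = 0.4,
                       abundance_scale = 5, count_noise = 1,
                       dropout_prob = 0.35, n_engines = 3L,
                       n_proteins = NULL, seed = 1L) {
  if (n_fractions < 4L) stop("n_fractions must be >= 4")
  if (dropout_prob < 0 || dropout_prob >= 1) stop("dropout_prob must be in [0, 1)")
  if (complex_size_range[1L] < 3L) stop("minimum complex size is 3")
  if (complex_size_range[2L] < complex_size_range[1L])
    stop("complex_size_range must be (min, max) with min <= max")
  if (apex_jitter > 1) stop("apex_jitter is bounded at 1 fraction")
  cfg <- list(n_complexes = as.integer(n_complexes),
              complex_size_range = as.integer(complex_size_range),
              n_background_proteins = as.integer(n_background_proteins),
              n_fractions = as.integer(n_fractions),
              peak_width_range = peak_width_range,
              apex_jitter = apex_jitter,
              abundance_scale = abundance_scale,
              count_noise = count_noise, dropout_prob = dropout_prob,
              n_engines = as.integer(n_engines),
              n_proteins = if (is.null(n_proteins)) NULL else as.integer(n_proteins),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

MITO_LABELS <- c("matrix", "IMS", "inner_membrane", "OMM")

random_apex <- function(n, n_fractions) stats::runif(n, 3, n_fractions - 2)
random_width <- function(n, range) stats::runif(n, range[1L], range[2L])

#' Generate planted ground truth with genotype-specific complex rewiring
#'
#' Builds a baseline ("WT") catalog of disjoint complexes plus one rewired
#' catalog per non-reference genotype. Per complex and genotype, an action is
#' drawn from the rewiring spec: `kept` (unchanged), `deleted` (members
#' dissolve into background), `split` (two disjoint subsets of >= 2 members
#' with distinct elution apexes; complexes of size 3 cannot split and fall
#' back to `kept`), or `apex_shifted` (whole complex moved >= 10 fractions).
#' Every protein receives exactly one subcompartment label (complex members
#' share their complex's label).
#'
#' @param config a [sim_config()].
#' @param rewiring_spec named list, genotype -> named numeric vector of
#'   action probabilities among `deleted` / `split` / `apex_shifted`
#'   (remaining mass is `kept`; must sum to <= 1).
#' @return a `planted_truth` list: `catalogs` (per genotype), `complex_params`
#'   (genotype, complex_id, apex, width), `rewiring_log`, `compartments`,
#'   `proteins`, `background`, `genotypes`, `config`.
#' @export
generate_truth <- function(config,
                           rewiring_spec = list(HOM = c(deleted = 0.3,
                                                        split = 0.1,
                                                        apex_shifted = 0.1))) {
  stopifnot(inherits(config, "sim_config"))
  for (g in names(rewiring_spec)) {
    pr <- rewiring_spec[[g]]
    bad <- setdiff(names(pr), c("deleted", "split", "apex_shifted"))
    if (length(bad)) stop("unknown rewiring action(s): ", paste(bad, collapse = ", "))
    if (sum(pr) > 1 + 1e-12)
      stop("rewiring probabilities for ", g, " sum to more than 1")
  }
  local_seed(derive_seed(config$seed, "truth"), {
    sizes <- if (config$n_complexes)
      sample(seq(config$complex_size_range[1L], config$complex_size_range[2L]),
             config$n_complexes, replace = TRUE) else integer()
    need <- sum(sizes) + config$n_background_proteins
    if (!is.null(config$n_proteins) && need > config$n_proteins)
      stop("complex size range infeasible for available protein pool (need ",
           need, " proteins, pool has ", config$n_proteins, ")")
    proteins <- sprintf("P%04d", seq_len(need))
    members <- split(proteins[seq_len(sum(sizes))],
                     rep(seq_along(sizes), sizes))
    names(members) <- sprintf("CPX%03d", seq_along(members))
    background <- proteins[seq_len(config$n_background_proteins) + sum(sizes)]
    baseline <- complex_catalog(members, source = "planted")
    compartments <- character(length(proteins))
    names(compartments) <- proteins
    for (id in names(members))
      compartments[members[[id]]] <- sample(MITO_LABELS, 1L)
    compartments[background] <- sample(c(MITO_LABELS, "non_mito"),
                                       length(background), replace = TRUE)
    genotypes <- c("WT", names(rewiring_spec))
    params <- list()
    catalogs <- list()
    log_rows <- list()
    base_apex <- random_apex(length(members), config$n_fractions)
    base_width <- random_width(length(members), config$peak_width_range)
    for (g in genotypes) {
      pr <- c(deleted = 0, split = 0, apex_shifted = 0)
      if (g != "WT") pr[names(rewiring_spec[[g]])] <- rewiring_spec[[g]]
      entries <- list(); rows <- list(); prow <- list()
      for (i in seq_along(members)) {
        id <- names(members)[i]
        action <- if (g == "WT") "kept" else
          sample(c("kept", names(pr)), 1L, prob = c(1 - sum(pr), pr))
        if (action == "split" && length(members[[id]]) < 4L) action <- "kept"
        if (action == "kept") {
          entries[[id]] <- members[[id]]
          prow[[id]] <- data.frame(genotype = g, complex_id = id,
                                   apex = base_apex[i], width = base_width[i])
        } else if (action == "apex_shifted") {
          entries[[id]] <- members[[id]]
          shift <- (10 + stats::runif(1, 0, 10)) *
            sample(c(-1, 1), 1L)
          apex <- base_apex[i] + shift
          if (apex < 3 || apex > config$n_fractions - 2)
            apex <- base_apex[i] - shift
          apex <- min(max(apex, 3), config$n_fractions - 2)
          prow[[id]] <- data.frame(genotype = g, complex_id = id,
                                   apex = apex, width = base_width[i])
        } else if (action == "split") {
          m <- members[[id]]
          cuts <- seq(2L, length(m) - 2L)
          cut <- cuts[sample.int(length(cuts), 1L)]
          parts <- list(a = m[seq_len(cut)], b = m[-seq_len(cut)])
          for (s in names(parts)) {
            sid <- paste0(id, ".", s)
            entries[[sid]] <- parts[[s]]
            prow[[sid]] <- data.frame(genotype = g, complex_id = sid,
                                      apex = random_apex(1L, config$n_fractions),
                                      width = random_width(1L, config$peak_width_range))
          }
        }                                  # deleted: absent from catalog
        rows[[id]] <- data.frame(genotype = g, complex_id = id,
                                 action = action, stringsAsFactors = FALSE)
      }
      catalogs[[g]] <- complex_catalog(entries, source = "planted")
      params[[g]] <- if (length(prow)) do.call(rbind, prow) else
        data.frame(genotype = character(), complex_id = character(),
                   apex = numeric(), width = numeric())
      log_rows[[g]] <- if (length(rows)) do.call(rbind, rows) else
        data.frame(genotype = character(), complex_id = character(),
                   action = character(), stringsAsFactors = FALSE)
    }
    truth <- list(catalogs = catalogs,
                  complex_params = do.call(rbind, c(params, list(make.row.names = FALSE))),
                  rewiring_log = do.call(rbind, c(log_rows, list(make.row.names = FALSE))),
                  compartments = compartments, proteins = proteins,
                  background = background, genotypes = genotypes,
                  config = config)
    class(truth) <- "planted_truth"
    truth
  })
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf("planted_truth: %d proteins, genotypes %s, %d baseline complexes\n",
              length(x$proteins), paste(x$genotypes, collapse = "/"),
              length(x$catalogs[["WT"]])))
  invisible(x)
}

#' Planted intra-complex pairs for one genotype
#' @param truth a `planted_truth`.
#' @param genotype genotype label present in the truth.
#' @return data.frame of canonical pairs (`protein_a`, `protein_b`).
#' @export
truth_edges <- function(truth, genotype) {
  if (!genotype %in% truth$genotypes) stop("unknown genotype ", genotype)
  catalog_pairs(truth$catalogs[[genotype]])
}

#' Simulate per-engine elution matrices for one genotype
#'
#' Members of a surviving complex share a Gaussian elution peak (the
#' complex's apex, with a small per-member apex jitter) with member-specific
#' lognormal amplitudes; background proteins and dissolved (deleted) complex
#' members get independent random apexes. Per engine, counts are drawn from
#' a gamma-Poisson (negative binomial) mixture at the profile mean when
#' `count_noise > 0` (noise-free continuous profiles when 0), and dropout
#' zeroes cells independently. The underlying mean profile is shared across
#' engines; only the noise differs.
#'
#' @param truth a `planted_truth` from [generate_truth()].
#' @param config the [sim_config()] used to generate it.
#' @param genotype genotype to simulate.
#' @param extract extract label for the matrices' metadata.
#' @param seed RNG seed; defaults to one derived from `config$seed` and the
#'   genotype, so different genotypes get independent streams.
#' @return list of [elution_matrix()] objects, one per engine.
#' @export
simulate_elution <- function(truth, config, genotype, extract = "Mt",
                             seed = NULL) {
  if (!genotype %in% truth$genotypes) stop("unknown genotype ", genotype)
  if (is.null(seed))
    seed <- derive_seed(config$seed, paste0("elution:", genotype))
  catalog <- truth$catalogs[[genotype]]
  params <- truth$complex_params
  params <- params[params$genotype == genotype, , drop = FALSE]
  nf <- config$n_fractions
  proteins <- truth$proteins
  local_seed(seed, {
    apex <- random_apex(length(proteins), nf)       # background default
    width <- random_width(length(proteins), config$peak_width_range)
    names(apex) <- names(width) <- proteins
    for (id in names(catalog)) {
      m <- catalog[[id]]
      p <- params[params$complex_id == id, ]
      apex[m] <- p$apex + stats::runif(length(m), -config$apex_jitter,
                                       config$apex_jitter)
      width[m] <- p$width
    }
    amp <- stats::rlnorm(length(proteins), log(config$abundance_scale), 0.5)
    fr <- seq_len(nf)
    lambda <- amp * exp(-outer(apex, fr, `-`)^2 / (2 * width^2))
    dimnames(lambda) <- list(proteins, sprintf("fraction_%03d", fr))
    lapply(seq_len(config$n_engines), function(e) {
      vals <- lambda
      if (config$count_noise > 0) {
        g <- matrix(stats::rgamma(length(vals), shape = 1 / config$count_noise,
                                  scale = config$count_noise),
                    nrow(vals), ncol(vals))
        vals[] <- stats::rpois(length(vals), as.vector(lambda * g))
      }
      if (config$dropout_prob > 0)
        vals[matrix(stats::runif(length(vals)) < config$dropout_prob,
                    nrow(vals), ncol(vals))] <- 0
      elution_matrix(vals, genotype = genotype, extract = extract,
                     engine = sprintf("engine%d", e))
    })
  })
}

#' Noise-free planted PPI network for one genotype
#'
#' Builds the idealized scored network implied by the planted truth: every
#' intra-complex pair at `within_score`, plus random background pairs at
#' `background_score`. Used to exercise the clustering and differential
#' stages with a known answer.
#'
#' @param truth a `planted_truth`.
#' @param genotype genotype label.
#' @param within_score,background_score edge scores (defaults 0.95 / 0.05).
#' @param n_background_edges random non-planted pairs to add (default: as
#'   many as there are planted pairs).
#' @param seed RNG seed for background edge sampling.
#' @return a [scored_network()].
#' @export
planted_network <- function(truth, genotype, within_score = 0.95,
                            background_score = 0.05,
                            n_background_edges = NULL, seed = 1L) {
  pairs <- truth_edges(truth, genotype)
  if (is.null(n_background_edges)) n_background_edges <- nrow(pairs)
  prot <- truth$proteins
  planted_key <- paste(pairs$protein_a, pairs$protein_b)
  bg <- local_seed(derive_seed(seed, paste0("bg:", genotype)), {
    out <- data.frame(protein_a = character(), protein_b = character())
    tries <- 0L
    while (nrow(out) < n_background_edges && tries < 20L) {
      a <- sample(prot, n_background_edges * 2L, replace = TRUE)
      b <- sample(prot, n_background_edges * 2L, replace = TRUE)
      ok <- a != b
      lo <- pmin(a, b)[ok]; hi <- pmax(a, b)[ok]
      cand <- unique(data.frame(protein_a = lo, protein_b = hi,
                                stringsAsFactors = FALSE))
      cand <- cand[!paste(cand$protein_a, cand$protein_b) %in% planted_key, ,
                   drop = FALSE]
      out <- unique(rbind(out, cand))
      tries <- tries + 1L
    }
    utils::head(out, n_background_edges)
  })
  edges <- rbind(
    data.frame(pairs, score = within_score, stringsAsFactors = FALSE),
    if (nrow(bg)) data.frame(bg, score = background_score) else NULL)
  scored_network(edges, threshold = 0, genotype = genotype, extract = "Mt")
}

#' Simulate spot-level counts with planted DEGs
#'
#' Negative-binomial spot counts for two groups, with a fraction of genes
#' planted as DEGs (their test-group mean multiplied by
#' `2^(+/- effect_size)`). Marker genes (high in the target region, near-zero
#' elsewhere) and a control region are included so that marker/region/soma
#' spot selection is exercisable; soma flags are true for most target-region
#' spots.
#'
#' @param n_per_group spots per group in the target region (>= 3).
#' @param n_genes number of non-marker genes.
#' @param deg_frac fraction of genes planted as DEGs, in [0, 1].
#' @param effect_size planted |log2 fold change|.
#' @param seed RNG seed.
#' @param groups two group labels (test, reference).
#' @param region,control_region region labels.
#' @param markers marker gene names declared for the target region.
#' @param dispersion negative-binomial size parameter.
#' @param soma_frac fraction of target-region spots flagged as containing a
#'   complete soma.
#' @return list with `spots` (a [spot_expression()]) and `deg_truth` (named
#'   vector gene -> planted signed log2 effect; empty when `deg_frac = 0`).
#' @export
simulate_spots <- function(n_per_group = 20L, n_genes = 2000L,
                           deg_frac = 0.1, effect_size = 2, seed = 1L,
                           groups = c("HOM", "WT"), region = "SN",
                           control_region = "thalamus",
                           markers = c("Th", "Slc6a3", "Slc18a2"),
                           dispersion = 5, soma_frac = 0.9) {
  if (n_per_group < 3L) stop("n_per_group must be >= 3")
  if (deg_frac < 0 || deg_frac > 1) stop("deg_frac must be in [0, 1]")
  local_seed(seed, {
    genes <- c(markers, sprintf("G%05d", seq_len(n_genes)))
    base_mu <- c(stats::setNames(rep(50, length(markers)), markers),
                 stats::setNames(stats::rlnorm(n_genes, log(5), 1),
                                 genes[-seq_along(markers)]))
    n_deg <- floor(deg_frac * n_genes)
    deg_genes <- sample(genes[-seq_along(markers)], n_deg)
    deg_truth <- stats::setNames(
      effect_size * sample(c(-1, 1), n_deg, replace = TRUE), deg_genes)
    n_ctrl <- ceiling(n_per_group / 4)
    meta <- data.frame(
      spot = sprintf("S%03d", seq_len(2L * (n_per_group + n_ctrl))),
      region = rep(c(region, control_region, region, control_region),
                   c(n_per_group, n_ctrl, n_per_group, n_ctrl)),
      group = rep(groups, each = n_per_group + n_ctrl),
      stringsAsFactors = FALSE)
    soma <- rep(TRUE, nrow(meta))
    in_region <- meta$region == region
    soma[in_region] <- stats::runif(sum(in_region)) < soma_frac
    # guarantee enough analyzable spots per group
    for (g in groups) {
      i <- which(in_region & meta$group == g)
      soma[i[seq_len(min(3L, length(i)))]] <- TRUE
    }
    soma[!in_region] <- stats::runif(sum(!in_region)) < 0.5
    meta$soma_flag <- soma
    counts <- matrix(0L, nrow(meta), length(genes),
                     dimnames = list(meta$spot, genes))
    for (i in seq_len(nrow(meta))) {
      mu <- base_mu
      if (meta$group[i] == groups[1L] && length(deg_genes))
        mu[deg_genes] <- mu[deg_genes] * 2^deg_truth
      if (meta$region[i] != region) mu[markers] <- 0.2
      counts[i, ] <- stats::rnbinom(length(genes), mu = mu, size = dispersion)
    }
    list(spots = spot_expression(counts, meta, marker_genes = markers),
         deg_truth = deg_truth)
  })
}
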