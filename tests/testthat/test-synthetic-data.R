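# Planted-truth generators: determinism, rewiring semantics, and the
# signal/noise behaviour of the simulated co-elution profiles.

small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_complexes = 8L, complex_size_range = c(3L, 6L),
         n_background_proteins = 20L, n_fractions = 48L, n_engines = 2L,
         seed = 7L), list(...))
  do.call(sim_config, args)
}

test_that("truth generation handles empty, forced, and repeated runs", {
  empty <- generate_truth(small_cfg(n_complexes = 0L), list(HOM = c(deleted = 1)))
  expect_length(empty$catalogs$WT, 0)
  expect_equal(nrow(empty$rewiring_log), 0)

  forced <- generate_truth(small_cfg(), list(HOM = c(deleted = 1)))
  hom <- forced$rewiring_log[forced$rewiring_log$genotype == "HOM", ]
  expect_true(all(hom$action == "deleted"))
  expect_length(forced$catalogs$HOM, 0)

  t1 <- generate_truth(small_cfg(n_complexes = 50L, seed = 7L))
  t2 <- generate_truth(small_cfg(n_complexes = 50L, seed = 7L))
  expect_identical(t1$catalogs, t2$catalogs)
  expect_identical(t1$complex_params, t2$complex_params)
})

test_that("truth invariants hold: labels, sizes, rewiring soundness", {
  cfg <- small_cfg(seed = 3L)
  tr <- generate_truth(cfg, list(HOM = c(deleted = 0.5, split = 0.3,
                                         apex_shifted = 0.2)))
  # every protein in a complex has exactly one compartment label
  members <- unique(unlist(tr$catalogs))
  expect_true(all(members %in% names(tr$compartments)))
  expect_true(all(tr$compartments %in%
                    c("OMM", "IMS", "matrix", "inner_membrane", "non_mito")))
  expect_true(all(lengths(tr$catalogs$WT) >= 3))
  # replaying the log reproduces each genotype's catalog
  log_hom <- tr$rewiring_log[tr$rewiring_log$genotype == "HOM", ]
  replay <- list()
  for (i in seq_len(nrow(log_hom))) {
    id <- log_hom$complex_id[i]
    act <- log_hom$action[i]
    if (act %in% c("kept", "apex_shifted")) replay[[id]] <- tr$catalogs$WT[[id]]
    if (act == "split") {
      for (s in c(".a", ".b")) replay[[paste0(id, s)]] <-
          tr$catalogs$HOM[[paste0(id, s)]]
      expect_true(all(lengths(replay[paste0(id, c(".a", ".b"))]) >= 2))
      expect_setequal(unlist(replay[paste0(id, c(".a", ".b"))]),
                      tr$catalogs$WT[[id]])
    }
  }
  expect_setequal(names(replay), names(tr$catalogs$HOM))
  # deleted complexes contribute no pairs to that genotype's truth edges
  deleted <- log_hom$complex_id[log_hom$action == "deleted"]
  hom_keys <- with(truth_edges(tr, "HOM"), paste(protein_a, protein_b))
  for (id in deleted) {
    pairs <- catalog_pairs(complex_catalog(tr$catalogs$WT[id], "planted"))
    expect_false(any(paste(pairs$protein_a, pairs$protein_b) %in% hom_keys))
  }
})

test_that("rewiring probabilities above 1 and unknown genotypes are rejected", {
  expect_error(generate_truth(small_cfg(), list(HOM = c(deleted = 0.8, split = 0.4))),
               "sum to more than 1")
  tr <- generate_truth(small_cfg())
  expect_error(simulate_elution(tr, small_cfg(), "KO"), "unknown genotype")
  expect_error(truth_edges(tr, "KO"), "unknown genotype")
})

test_that("pool cap makes oversized complex demands infeasible", {
  expect_error(generate_truth(small_cfg(n_proteins = 10L)), "infeasible")
})

test_that("noise-free co-complex members co-elute almost perfectly", {
  cfg <- small_cfg(count_noise = 0, dropout_prob = 0, seed = 11L)
  tr <- generate_truth(cfg)
  m <- simulate_elution(tr, cfg, "WT")[[1]]
  expect_true(all(m >= 0))
  for (id in names(tr$catalogs$WT)) {
    prof <- unclass(m)[tr$catalogs$WT[[id]], , drop = FALSE]
    cors <- cor(t(prof))
    expect_gt(min(cors[upper.tri(cors)]), 0.99)
  }
})

test_that("deleted-complex members decorrelate in the mutant genotype", {
  # default noise/dropout: dissolved members keep broad SEC-like peaks, so
  # only the count noise and independent apexes separate them
  cfg <- small_cfg(n_complexes = 12L, n_fractions = 96L, seed = 13L)
  tr <- generate_truth(cfg, list(HOM = c(deleted = 1)))
  m <- simulate_elution(tr, cfg, "HOM")[[1]]
  vals <- numeric()
  for (id in names(tr$catalogs$WT)) {
    prof <- unclass(m)[tr$catalogs$WT[[id]], , drop = FALSE]
    cors <- cor(t(prof))
    vals <- c(vals, abs(cors[upper.tri(cors)]))
  }
  expect_lt(mean(vals), 0.3)
})

test_that("lowering noise never lowers mean within-complex correlation", {
  grid <- list(c(0, 0), c(1, 0.2), c(3, 0.5))   # (count_noise, dropout)
  mean_cor <- vapply(grid, function(g) {
    cfg <- small_cfg(count_noise = g[1], dropout_prob = g[2], seed = 17L)
    tr <- generate_truth(cfg)
    m <- simulate_elution(tr, cfg, "WT", seed = 99L)[[1]]
    vals <- numeric()
    for (id in names(tr$catalogs$WT)) {
      cors <- cor(t(unclass(m)[tr$catalogs$WT[[id]], , drop = FALSE]))
      vals <- c(vals, cors[upper.tri(cors)])
    }
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(mean_cor) <= 0))
})

test_that("elution simulation is reproducible and engine draws differ", {
  cfg <- small_cfg(seed = 23L)
  tr <- generate_truth(cfg)
  a <- simulate_elution(tr, cfg, "WT")
  b <- simulate_elution(tr, cfg, "WT")
  expect_identical(lapply(a, unclass), lapply(b, unclass))
  expect_false(identical(unclass(a[[1]]), unclass(a[[2]])))
})

test_that("spot simulation honours its contracts", {
  s1 <- simulate_spots(n_per_group = 6L, n_genes = 100L, seed = 5L)
  s2 <- simulate_spots(n_per_group = 6L, n_genes = 100L, seed = 5L)
  expect_identical(s1$spots$counts, s2$spots$counts)
  expect_length(simulate_spots(n_per_group = 6L, n_genes = 50L,
                               deg_frac = 0, seed = 1L)$deg_truth, 0)
  expect_error(simulate_spots(n_per_group = 2L), ">= 3")
  expect_error(simulate_spots(deg_frac = 1.5), "deg_frac")
})

test_that("a null effect leaves planted 'DEGs' at the false-positive rate", {
  sim <- simulate_spots(n_per_group = 15L, n_genes = 600L, deg_frac = 0.2,
                        effect_size = 0, seed = 31L)
  sel <- select_spots(sim$spots, "SN")
  tab <- call_degs(score_genes(gene_stats(sel, "HOM", "WT")))
  called <- tab$gene[tab$deg_flag]
  hit_rate <- mean(names(sim$deg_truth) %in% called)
  fp_rate <- mean(setdiff(tab$gene, names(sim$deg_truth)) %in% called)
  expect_lt(abs(hit_rate - fp_rate), 0.05)
})
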