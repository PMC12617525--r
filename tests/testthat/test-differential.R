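# Differential layer: Venn-style intersections, lost-interaction
# attribution, the abundance-shift ranking, and GSEA against brute-force
# and fgsea oracles.

mknet <- function(edges, genotype, extract = "Mt")
  scored_network(data.frame(protein_a = edges[c(TRUE, FALSE)],
                            protein_b = edges[c(FALSE, TRUE)], score = 0.9),
                 genotype = genotype, extract = extract)

test_that("intersections classify edges by exact presence pattern", {
  a <- mknet(c("A", "B", "B", "C"), "WT")
  b <- mknet(c("A", "B", "B", "C"), "HOM")
  ident <- intersect_networks(list(WT = a, HOM = b))
  expect_length(ident$cells, 1)
  expect_equal(ident$cells[["WT&HOM"]], 2, ignore_attr = TRUE)
  expect_equal(ident$n_union, 2)

  disj <- intersect_networks(list(WT = a, HOM = mknet(c("X", "Y"), "HOM")))
  expect_setequal(names(disj$cells), c("WT", "HOM"))

  expect_error(intersect_networks(list(WT = a,
                                       HOM = mknet(c("X", "Y"), "HOM", "WTL"))),
               "mixed extracts")
})

test_that("three-genotype intersection counts match exhaustive enumeration", {
  nets <- list(WT  = mknet(c("A","B", "B","C", "C","D", "D","E"), "WT"),
               HET = mknet(c("A","B", "C","D", "E","F"), "HET"),
               HOM = mknet(c("B","C", "C","D", "E","F", "A","F"), "HOM"))
  rep <- intersect_networks(nets)
  # brute force: classify each union edge by membership
  keys <- lapply(nets, edge_keys <- function(n) paste(n$protein_a, n$protein_b, sep = "|"))
  uni <- unique(unlist(keys))
  patt <- sapply(uni, function(k)
    paste(names(nets)[sapply(keys, function(x) k %in% x)], collapse = "&"))
  expect_equal(sum(unlist(rep$cells)), length(uni))
  for (cell in names(rep$cells))
    expect_equal(rep$cells[[cell]], sum(patt == cell), label = cell)
})

test_that("lost interactions and hub attribution follow the hand counts", {
  a <- mknet(c("A","B", "B","C", "C","D"), "WT")
  none <- lost_interactions(a, list(a))
  expect_equal(none$n_lost, 0)
  expect_length(none$hub_percent, 0)

  hub <- mknet(c("H","P1", "H","P2", "H","P3", "H","P4", "H","P5",
                 "P6","P7", "P6","P8", "P6","P9", "P7","P8", "P9","P7"), "WT")
  empty <- scored_network(data.frame(protein_a = character(),
                                     protein_b = character(),
                                     score = numeric()),
                          genotype = "HOM", extract = "Mt")
  lost <- lost_interactions(hub, list(empty))
  expect_equal(lost$n_lost, 10)
  expect_equal(unname(lost$hub_percent["H"]), 50)   # 5 of 10 lost edges
  expect_equal(sum(lost$hub_percent), 200)          # both endpoints tallied
  expect_setequal(lost$involved_proteins,
                  c("H", paste0("P", 1:9)))
})

test_that("a complex deleted in the mutant shows up fully in the lost set", {
  cfg <- sim_config(n_complexes = 6L, n_background_proteins = 10L,
                    n_fractions = 48L, seed = 29L)
  tr <- generate_truth(cfg, list(HOM = c(deleted = 0.5)))
  wt <- planted_network(tr, "WT", background_score = 0, n_background_edges = 0)
  hom <- planted_network(tr, "HOM", background_score = 0, n_background_edges = 0)
  lost <- lost_interactions(wt, list(hom))
  lost_keys <- paste(lost$lost$protein_a, lost$lost$protein_b)
  log <- tr$rewiring_log
  deleted <- log$complex_id[log$genotype == "HOM" & log$action == "deleted"]
  expect_gt(length(deleted), 0)
  for (id in deleted) {
    pairs <- catalog_pairs(complex_catalog(tr$catalogs$WT[id], "planted"))
    expect_true(all(paste(pairs$protein_a, pairs$protein_b) %in% lost_keys))
  }
})

test_that("the ranking statistic matches direct arithmetic", {
  a <- toy_matrix(c(1, 2, 3, 4, 5, 6), proteins = c("P", "Q"))
  expect_equal(rank_proteins(a, a), c(P = 0, Q = 0))
  b10 <- elution_matrix(matrix(c(4, 6), 1, 2, dimnames = list("P", NULL)))
  b40 <- elution_matrix(matrix(c(15, 25), 1, 2, dimnames = list("P", NULL)))
  expect_equal(unname(rank_proteins(b10, b40)["P"]), log2(41 / 11))
  # a protein absent from both matrices sits at the epsilon floor
  onlyb <- elution_matrix(matrix(c(0, 0), 1, 2, dimnames = list("R", NULL)))
  r <- rank_proteins(b10, onlyb)
  expect_equal(unname(r["R"]), 0)          # log2(1/1)
  expect_true(all(is.finite(rank_proteins(b40, onlyb))))
})

test_that("GSEA finds the strongest possible set at minimal attainable p", {
  rk <- withr::with_seed(41, setNames(rnorm(200), sprintf("G%03d", 1:200)))
  top <- names(sort(rk, decreasing = TRUE))[1:12]
  sets <- complex_catalog(list(top = top), "reference")
  res <- complex_gsea(rk, sets, n_perm = 500, seed = 2)
  expect_gt(res$es, 0)
  expect_lte(res$p, 2 / 501)              # nothing can beat the top-k set
  expect_equal(res$direction, "up")
})

test_that("the unweighted ES equals a direct KS computation on a toy ranking", {
  rk <- withr::with_seed(43, setNames(rnorm(20), letters[1:20]))
  for (seed in 1:10) {
    set <- withr::with_seed(seed, sample(names(rk), 5))
    mine <- complex_gsea(rk, complex_catalog(list(s = set), "reference"),
                         n_perm = 100, weight_exponent = 0, seed = 1)
    expect_equal(mine$es, unname(oracle_es(rk, set, 0)), tolerance = 1e-12)
    w1 <- complex_gsea(rk, complex_catalog(list(s = set), "reference"),
                       n_perm = 100, weight_exponent = 1, seed = 1)
    expect_equal(w1$es, unname(oracle_es(rk, set, 1)), tolerance = 1e-12)
  }
})

test_that("ES agrees with fgsea on random sets", {
  skip_if_not_installed("fgsea")
  rk <- withr::with_seed(47, setNames(rnorm(100), sprintf("G%03d", 1:100)))
  sets <- withr::with_seed(48, lapply(1:5, function(i) sample(names(rk), 8)))
  names(sets) <- paste0("S", 1:5)
  mine <- complex_gsea(rk, complex_catalog(sets, "reference"),
                       n_perm = 100, weight_exponent = 1, seed = 1)
  ref <- suppressWarnings(fgsea::fgseaSimple(sets, rk, nperm = 10,
                                             gseaParam = 1))
  expect_equal(mine$es[match(ref$pathway, mine$complex_id)], ref$ES,
               tolerance = 1e-9)
})

test_that("raising a set's member statistics never lowers its ES", {
  rk <- setNames(seq(2, -2, length.out = 30), sprintf("g%02d", 1:30))
  set <- c("g10", "g15", "g20", "g25")
  base <- oracle_es(rk, set, 1)
  rk2 <- rk; rk2[set] <- rk2[set] + 1.5
  expect_gte(oracle_es(rk2, set, 1), base)
  mine <- complex_gsea(rk2, complex_catalog(list(s = set), "reference"),
                       n_perm = 100, seed = 3)
  expect_gte(mine$es, complex_gsea(rk, complex_catalog(list(s = set), "reference"),
                                   n_perm = 100, seed = 3)$es)
})

test_that("small complexes are skipped and runs are seed-stable", {
  rk <- setNames(rnorm(50), sprintf("g%02d", 1:50))
  sets <- complex_catalog(list(ok = c("g01", "g02", "g03"),
                               tiny = c("g04", "zzz")), "reference")
  a <- complex_gsea(rk, sets, n_perm = 200, seed = 5)
  expect_equal(attr(a, "skipped"), "tiny")
  expect_equal(a$complex_id, "ok")
  b <- complex_gsea(rk, sets, n_perm = 200, seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_error(complex_gsea(rk, sets, n_perm = 10), ">= 100")
})

test_that("exclusive assemblies are those unmatched in other genotypes", {
  cats <- list(
    WT  = complex_catalog(list(C1 = c("A", "B", "C"), C2 = c("D", "E", "F")),
                          "predicted"),
    HOM = complex_catalog(list(K1 = c("A", "B", "C")), "predicted"))
  excl <- exclusive_assemblies(cats)
  expect_equal(names(excl$WT), "C2")
  expect_length(excl$HOM, 0)
})
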