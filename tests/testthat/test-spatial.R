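# FCS/SNS scoring: spot selection rules, group statistics against the
# textbook t test, exact formula checks, the dual top-20% DEG rule, and
# scale invariance of the whole chain.

toy_spots <- function() {
  counts <- matrix(c(
    # Th  Dat  g1  g2
      5,   4,  10,  0,
      6,   5,  12,  1,
      0,   4,   8,  2,   # Th below floor 1? no: floor tests use >= 1
      5,   5,   9,  1,
      7,   6,  11,  0,
      5,   4,  10,  2), 6, 4, byrow = TRUE,
    dimnames = list(sprintf("S%d", 1:6), c("Th", "Dat", "g1", "g2")))
  meta <- data.frame(spot = sprintf("S%d", 1:6),
                     region = c("SN", "SN", "SN", "SN", "thal", "SN"),
                     group = c("HOM", "HOM", "HOM", "WT", "WT", "WT"),
                     soma_flag = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  spot_expression(counts, meta, marker_genes = c("Th", "Dat"))
}

test_that("spot selection applies region, soma, and marker rules exactly", {
  sp <- toy_spots()
  sel <- select_spots(sp, "SN", marker_floor = 1)
  # manual application: S5 wrong region, S6 no soma, S3 has Th = 0
  expect_setequal(sel$meta$spot, c("S1", "S2", "S4"))
  # marker_floor 0 keeps S3 (only region/soma act)
  sel0 <- select_spots(sp, "SN", marker_floor = 0)
  expect_setequal(sel0$meta$spot, c("S1", "S2", "S3", "S4"))
  expect_error(select_spots(sp, "cortex"), "not present")
  strict <- spot_expression(sp$counts,
                            transform(sp$meta, soma_flag = FALSE),
                            sp$marker_genes)
  expect_error(select_spots(strict, "SN"), "no spot survives")
})

test_that("group statistics reproduce the textbook Welch t test", {
  counts <- matrix(c(1, 4, 2, 5, 3, 6), 6, 1,
                   dimnames = list(sprintf("S%d", 1:6), "g"))
  meta <- data.frame(spot = sprintf("S%d", 1:6),
                     region = "SN", group = rep(c("A", "B"), 3),
                     soma_flag = TRUE)
  sp <- spot_expression(counts, meta)
  st <- gene_stats(sp, "A", "B", normalization = "none")
  oracle <- t.test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(st$p, oracle$p.value, tolerance = 1e-12)
  expect_equal(st$mu_test, 2); expect_equal(st$mu_ref, 5)
  expect_equal(st$sd_test, 1)
  stud <- gene_stats(sp, "A", "B", normalization = "none", test = "student")
  expect_equal(stud$p, t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("degenerate groups follow the zero-variance and null conventions", {
  counts <- matrix(c(0, 0, 0, 0, 0, 0,
                     2, 2, 2, 2, 2, 2,
                     3, 3, 3, 5, 5, 5), 6, 3,
                   dimnames = list(sprintf("S%d", 1:6),
                                   c("allzero", "flat", "shifted")))
  meta <- data.frame(spot = sprintf("S%d", 1:6), region = "SN",
                     group = rep(c("A", "B"), each = 3), soma_flag = TRUE)
  st <- gene_stats(spot_expression(counts, meta), "A", "B",
                   normalization = "none")
  expect_equal(st$p[st$gene == "allzero"], 1)   # (0,0,0) vs (0,0,0)
  expect_equal(st$p[st$gene == "flat"], 1)
  expect_equal(st$p[st$gene == "shifted"], 1)   # zero variance, both groups
  expect_error(gene_stats(spot_expression(counts[1:3, ], meta[1:3, ]),
                          "A", "B"), "at least 2 spots")
})

test_that("FCS and SNS evaluate the formulas exactly", {
  st <- data.frame(gene = c("a", "b", "c"),
                   mu_test = c(4, 3, 1), mu_ref = c(1, 3, 2),
                   sd_test = c(1, 1, 0.5), sd_ref = c(1, 1, 0.5),
                   p = c(0.01, 0.5, 0.1))
  sc <- score_genes(st)
  expect_equal(sc$fcs[1], log2(4) * 2, tolerance = 1e-12)      # 4.0
  expect_equal(sc$fcs[2], 0); expect_equal(sc$sns[2], 0)       # no difference
  expect_equal(sc$sns[3], (-1 / 1) * 1, tolerance = 1e-12)     # -1.0
  # pseudocount engages only on zero denominators
  z <- score_genes(data.frame(gene = "z", mu_test = 3, mu_ref = 0,
                              sd_test = 0, sd_ref = 0, p = 0.1))
  expect_equal(z$fcs, log2(4) * 1)                             # (3+1)/(0+1)
  expect_equal(z$sns, 3 * 1)                                   # sigma sum -> 1
  expect_true(all(is.finite(c(z$fcs, z$sns))))
})

test_that("the dual top-20% DEG rule matches exhaustive manual application", {
  tab <- structure(data.frame(
    gene = sprintf("g%02d", 1:10),
    mu_test = 1, mu_ref = 1, sd_test = 1, sd_ref = 1,
    p   = c(0.01, 0.20, 0.01, 0.03, 0.01, 0.04, 0.50, 0.01, 0.04, 0.30),
    fcs = c(5.0,  4.5,  4.0,  3.0,  2.0,  1.0,  0.5,  0.4,  0.3,  0.2),
    sns = c(3.0,  0.1,  2.5,  0.2,  2.0,  0.3,  2.2,  0.1,  0.2,  0.1)),
    class = c("deg_score_table", "data.frame"))
  out <- call_degs(tab)                     # cutoff = ceiling(0.2 * 10) = 2
  # manual: FCS top-2 = {g01, g02}; SNS top-2 = {g01, g03}; P < 0.05 both
  expect_equal(out$gene[out$deg_flag], "g01")
  expect_equal(max(out$rank_fcs[out$deg_flag]), 1)
  # a gene top-ranked in one score only is never flagged
  expect_false(out$deg_flag[out$gene == "g03"])
  # ties share a dense rank
  tie <- tab; tie$fcs <- c(5, 5, rep(1, 8)); tie$sns <- c(3, 3, rep(0.1, 8))
  tie$p[2] <- 0.01
  out2 <- call_degs(tie)
  expect_equal(out2$rank_fcs[1:2], c(1, 1))      # tied scores share rank 1
  expect_true(all(c("g01", "g02") %in% out2$gene[out2$deg_flag]))
})

test_that("uniform rescaling of counts leaves scores and calls unchanged", {
  sim <- simulate_spots(n_per_group = 10L, n_genes = 150L, deg_frac = 0.2,
                        effect_size = 2, seed = 77L)
  sel <- select_spots(sim$spots, "SN")
  run <- function(counts) {
    sp <- spot_expression(counts, sel$meta, sel$marker_genes)
    call_degs(score_genes(gene_stats(sp, "HOM", "WT")))
  }
  base <- run(sel$counts)
  scaled <- run(sel$counts * 13)
  expect_equal(scaled$fcs, base$fcs, tolerance = 1e-9)
  expect_equal(scaled$sns, base$sns, tolerance = 1e-9)
  expect_identical(scaled$deg_flag, base$deg_flag)
  # sign coherence between the two scores away from pseudocounts
  ok <- base$mu_test > 0 & base$mu_ref > 0 & base$p < 1
  expect_true(all(sign(base$fcs[ok]) == sign(base$sns[ok]) |
                    base$fcs[ok] == 0))
})

test_that("null data yields a calibrated t-test rejection rate", {
  sim <- simulate_spots(n_per_group = 15L, n_genes = 800L, deg_frac = 0,
                        seed = 101L)
  sel <- select_spots(sim$spots, "SN")
  st <- gene_stats(sel, "HOM", "WT")
  rate <- mean(st$p < 0.05)
  expect_gt(rate, 0.01); expect_lt(rate, 0.10)
})
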