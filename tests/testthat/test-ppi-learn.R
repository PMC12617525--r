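# Classifier harness: training-set construction from a reference catalog,
# CV behaviour on separable and label-permuted data, threshold rules, and
# the compartment plausibility filter.

ref3 <- complex_catalog(list(C1 = c("A", "B", "C")), source = "reference")

separable_features <- function(n_pos, n_neg, seed = 1, noise = 0.01) {
  withr::with_seed(seed, {
    prot_p <- sprintf("pos%03d", seq_len(2 * n_pos))
    prot_n <- sprintf("neg%03d", seq_len(2 * n_neg))
    df <- data.frame(
      protein_a = c(prot_p[seq_len(n_pos)], prot_n[seq_len(n_neg)]),
      protein_b = c(prot_p[n_pos + seq_len(n_pos)], prot_n[n_neg + seq_len(n_neg)]),
      pearson = c(rnorm(n_pos, 1, noise), rnorm(n_neg, 0, noise)),
      apex_match = c(rnorm(n_pos, 1, noise), rnorm(n_neg, 0, noise)),
      stringsAsFactors = FALSE)
    training <- data.frame(protein_a = df$protein_a, protein_b = df$protein_b,
                           label = rep(c("positive", "negative"),
                                       c(n_pos, n_neg)))
    feats <- structure(df, class = c("pair_features", "data.frame"),
                       metrics = c("pearson", "apex_match"))
    list(features = feats, training = training)
  })
}

test_that("training pairs enumerate complexes and sample clean negatives", {
  # a one-complex reference has no cross-complex pairs to sample from
  expect_warning(ts <- build_training(ref3, c("A", "B", "C"), seed = 1),
                 "negative pool")
  pos <- ts[ts$label == "positive", ]
  expect_setequal(paste(pos$protein_a, pos$protein_b), c("A B", "A C", "B C"))
  expect_true(all(pos$provenance == "C1"))

  # a pair shared by two overlapping complexes appears once
  ref_ov <- complex_catalog(list(C1 = c("A", "B", "C"), C2 = c("A", "B", "D")),
                            source = "reference")
  ts2 <- suppressWarnings(build_training(ref_ov, c("A", "B", "C", "D"),
                                         seed = 1))
  key <- paste(ts2$protein_a, ts2$protein_b)
  expect_equal(anyDuplicated(key), 0)
  expect_equal(ts2$provenance[key == "A B"], "C1;C2")

  # 1:1 ratio on a two-complex reference: negatives span complexes
  ref2 <- complex_catalog(list(C1 = c("A", "B", "C"), C2 = c("D", "E", "F")),
                          source = "reference")
  ts3 <- build_training(ref2, LETTERS[1:6], negative_ratio = 1, seed = 3)
  neg <- ts3[ts3$label == "negative", ]
  expect_equal(nrow(neg), 6)
  intra <- paste(catalog_pairs(ref2)$protein_a, catalog_pairs(ref2)$protein_b)
  expect_false(any(paste(neg$protein_a, neg$protein_b) %in% intra))
  expect_identical(build_training(ref2, LETTERS[1:6], seed = 3),
                   build_training(ref2, LETTERS[1:6], seed = 3))
  expect_error(build_training(ref3, c("X", "Y")), "does not overlap")
})

test_that("separable features give perfect pooled CV auROC and Youden cut", {
  fx <- separable_features(30, 30, seed = 2)
  out <- train_and_score(fx$features, fx$training, k_folds = 5, seed = 2)
  expect_equal(unname(out$report$pooled_auroc["ensemble"]), 1.0)
  thr <- select_threshold(out$report, "youden")
  roc <- out$report$roc$ensemble
  best <- roc[which.max(roc$tpr - roc$fpr), ]
  expect_equal(best$tpr, 1); expect_equal(best$fpr, 0)
  expect_true(all(out$scores$ensemble >= 0 & out$scores$ensemble <= 1))
})

test_that("permuted labels collapse auROC to chance", {
  fx <- separable_features(1000, 1000, seed = 4, noise = 0.3)
  perm <- fx$training
  perm$label <- withr::with_seed(9, sample(perm$label))
  out <- train_and_score(fx$features, perm, models = c("rf", "glm"),
                         k_folds = 5, seed = 4)
  expect_lt(abs(out$report$pooled_auroc[["ensemble"]] - 0.5), 0.1)
})

test_that("scoring is deterministic and out-of-fold for labeled pairs", {
  fx <- separable_features(25, 25, seed = 6, noise = 0.5)
  a <- train_and_score(fx$features, fx$training, k_folds = 5, seed = 11)
  b <- train_and_score(fx$features, fx$training, k_folds = 5, seed = 11)
  expect_identical(a$scores, b$scores)
  expect_true(all(a$scores$cv))            # every pair here is labeled
  # fold assignment is stratified and complete
  expect_equal(sort(unique(a$report$fold)), 1:5)
  for (k in 1:5) {
    held <- fx$training$label[a$report$fold == k]
    expect_true(all(c("positive", "negative") %in% held))
  }
})

test_that("degenerate folds are rejected with guidance", {
  fx <- separable_features(3, 30, seed = 7)
  expect_error(train_and_score(fx$features, fx$training, k_folds = 5, seed = 1),
               "single class")
})

test_that("threshold rules behave as documented", {
  roc <- data.frame(cutoff = c(-Inf, 0.2, 0.4, 0.6, Inf),
                    tpr = c(1, 1, 0.9, 0.5, 0),
                    fpr = c(1, 0.5, 0.4, 0.1, 0))
  rep <- list(roc = list(ensemble = roc))
  expect_equal(select_threshold(rep, "fixed:0.84"), 0.84)
  # J ties at 0.4 (0.5) and 0.6 (0.4)? J: 0, .5, .5, .4, 0 -> tie 0.2 vs 0.4
  expect_equal(select_threshold(rep, "youden"), 0.4)  # higher cutoff wins
  expect_equal(select_threshold(rep, "fpr_at:0.4"), 0.4)
  expect_error(select_threshold(rep, "fpr_at:-1"), "no cutoff")
  expect_error(select_threshold(list(roc = list()), "youden"), "empty ROC")
  expect_error(select_threshold(rep, "nonsense"), "unknown threshold rule")
})

test_that("edge retention is nonincreasing in the threshold", {
  fx <- separable_features(20, 20, seed = 10, noise = 0.6)
  out <- train_and_score(fx$features, fx$training, k_folds = 4, seed = 3)
  counts <- vapply(seq(0, 1, by = 0.1), function(t)
    nrow(threshold_network(out$scores, t)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("implausible compartment pairs are vetoed, others pass", {
  net <- scored_network(data.frame(
    protein_a = c("m1", "i1", "i2", "u1"),
    protein_b = c("o1", "m1", "i1", "m1"),
    score = c(0.9, 0.8, 0.7, 0.6)))
  comp <- c(m1 = "matrix", o1 = "OMM", i1 = "IMS", i2 = "IMS")
  out <- filter_implausible(net, comp)
  expect_equal(nrow(out$removed), 2)
  expect_setequal(out$removed$reason, c("OMM-matrix", "IMS-matrix"))
  keys <- paste(out$network$protein_a, out$network$protein_b, sep = "|")
  expect_true("i1|i2" %in% keys)           # IMS-IMS retained
  expect_true("m1|u1" %in% keys)           # unannotated endpoint passes
  expect_equal(out$n_unannotated_passed, 1)
})
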