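# PPI classification: labeled pairs from a reference complex catalog, three
# classifiers (random forest, logistic GLM, RBF-SVM) plus their unweighted
# probability-mean ensemble, stratified fivefold cross-validation, ROC-based
# threshold selection, and subcompartment plausibility filtering.

#' Build a labeled training set from a reference complex catalog
#'
#' Positives are all unordered intra-complex pairs among detected proteins;
#' negatives are sampled uniformly without replacement from pairs of
#' reference-annotated detected proteins that share no complex (so every
#' negative spans two different complexes and is intra-complex in none).
#'
#' @param reference a [complex_catalog()] gold standard.
#' @param detected character vector of proteins present in the experiment.
#' @param negative_ratio negatives per positive (default 1).
#' @param seed RNG seed for negative sampling.
#' @return a `training_set` data.frame with columns `protein_a`, `protein_b`,
#'   `label` ("positive"/"negative") and `provenance` (complex ids generating
#'   a positive; "" for negatives).
#' @export
build_training <- function(reference, detected, negative_ratio = 1, seed = 1L) {
  detected <- unique(as.character(detected))
  annotated <- intersect(sort(unique(unlist(reference))), detected)
  pos <- catalog_pairs(reference)
  pos <- pos[pos$protein_a %in% detected & pos$protein_b %in% detected, ,
             drop = FALSE]
  if (!nrow(pos))
    stop("reference does not overlap detected proteins: no positive pairs")
  membership <- lapply(annotated, function(p)
    names(reference)[vapply(reference, function(m) p %in% m, logical(1))])
  names(membership) <- annotated
  prov <- vapply(seq_len(nrow(pos)), function(i)
    paste(intersect(membership[[pos$protein_a[i]]],
                    membership[[pos$protein_b[i]]]), collapse = ";"),
    character(1))
  idx <- utils::combn(seq_along(annotated), 2L)
  all_a <- annotated[idx[1L, ]]; all_b <- annotated[idx[2L, ]]
  pos_key <- paste(pos$protein_a, pos$protein_b)
  eligible <- !(paste(all_a, all_b) %in% pos_key)
  n_neg <- min(round(nrow(pos) * negative_ratio), sum(eligible))
  if (n_neg < round(nrow(pos) * negative_ratio))
    warning("negative pool smaller than requested ratio; using all ",
            n_neg, " eligible cross-complex pairs")
  idx <- which(eligible)
  pick <- local_seed(seed, idx[sample.int(length(idx), n_neg)])
  out <- data.frame(
    protein_a = c(pos$protein_a, all_a[pick]),
    protein_b = c(pos$protein_b, all_b[pick]),
    label = rep(c("positive", "negative"), c(nrow(pos), n_neg)),
    provenance = c(prov, rep("", n_neg)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("training_set", "data.frame"),
            negative_ratio = negative_ratio, seed = as.integer(seed))
}

fit_ppi_models <- function(X, y, models, svm_cost = 1, rf_trees = 500L) {
  fits <- list()
  if ("rf" %in% models)
    fits$rf <- randomForest::randomForest(x = X, y = y, ntree = rf_trees)
  if ("glm" %in% models) {
    dat <- data.frame(X, check.names = FALSE)
    fits$glm <- suppressWarnings(
      stats::glm(y ~ ., data = cbind(y = y, dat), family = stats::binomial()))
  }
  if ("svm" %in% models)
    fits$svm <- e1071::svm(x = X, y = y, kernel = "radial", cost = svm_cost,
                           probability = TRUE)
  fits
}

predict_ppi_models <- function(fits, X) {
  out <- list()
  if (!is.null(fits$rf))
    out$rf <- unname(stats::predict(fits$rf, X, type = "prob")[, "positive"])
  if (!is.null(fits$glm))
    out$glm <- unname(suppressWarnings(
      stats::predict(fits$glm, data.frame(X, check.names = FALSE),
                     type = "response")))
  if (!is.null(fits$svm)) {
    pr <- stats::predict(fits$svm, X, probability = TRUE)
    out$svm <- unname(attr(pr, "probabilities")[, "positive"])
  }
  lapply(out, function(p) pmin(pmax(p, 0), 1))
}

roc_points <- function(labels, scores) {
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c("negative", "positive"), direction = "<",
                 quiet = TRUE)
  data.frame(cutoff = r$thresholds, tpr = r$sensitivities,
             fpr = 1 - r$specificities)
}

auroc <- function(labels, scores) {
  as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                 levels = c("negative", "positive"),
                                 direction = "<", quiet = TRUE)))
}

#' Train PPI classifiers with cross-validation and score all candidate pairs
#'
#' Three classifiers -- a 500-tree random forest, a binomial (logistic)
#' generalized linear model, and a radial-basis SVM with probability
#' calibration -- are trained on the labeled pairs and combined as an
#' ensemble (unweighted mean of the three class probabilities). Labeled pairs
#' are scored strictly out-of-fold under stratified k-fold cross-validation
#' (a pair's reported score always comes from the fold in which it was held
#' out); unlabeled pairs are scored by models refit on all labeled pairs.
#'
#' @param features a `pair_features` table from [compute_features()] covering
#'   at least every training pair.
#' @param training a `training_set` from [build_training()].
#' @param models subset of `c("rf", "glm", "svm")` to train (the ensemble is
#'   always reported when more than one is trained).
#' @param k_folds number of CV folds (default 5).
#' @param seed RNG seed (fold assignment, forest, SVM calibration).
#' @return list with `scores` (data.frame: pairs, one column per model,
#'   `ensemble`, and `cv` flag marking out-of-fold scores) and `report` (a CV
#'   report: per-fold and pooled auROC per model, pooled ROC points, fold
#'   assignment, class sizes).
#' @export
train_and_score <- function(features, training,
                            models = c("rf", "glm", "svm"),
                            k_folds = 5L, seed = 1L) {
  models <- match.arg(models, c("rf", "glm", "svm"), several.ok = TRUE)
  if (k_folds < 2L) stop("k_folds must be >= 2")
  metrics <- attr(features, "metrics")
  if (is.null(metrics))
    metrics <- setdiff(names(features), c("protein_a", "protein_b"))
  fkey <- paste(features$protein_a, features$protein_b)
  tkey <- paste(training$protein_a, training$protein_b)
  miss <- setdiff(tkey, fkey)
  if (length(miss))
    stop("training pair(s) absent from feature table: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  Xall <- as.matrix(features[metrics])
  rownames(Xall) <- NULL
  ti <- match(tkey, fkey)
  y <- factor(training$label, levels = c("negative", "positive"))
  if (min(table(y)) < k_folds)
    stop("a CV fold would contain a single class; add training data or ",
         "reduce k_folds")
  local_seed(seed, {
    fold <- integer(length(y))
    for (lv in levels(y)) {
      i <- which(y == lv)
      fold[i] <- sample(rep_len(seq_len(k_folds), length(i)))
    }
    cv <- matrix(NA_real_, length(y), length(models),
                 dimnames = list(NULL, models))
    per_fold <- list()
    for (k in seq_len(k_folds)) {
      tr <- fold != k
      fits <- fit_ppi_models(Xall[ti[tr], , drop = FALSE], y[tr], models)
      pred <- predict_ppi_models(fits, Xall[ti[!tr], , drop = FALSE])
      for (m in models) cv[!tr, m] <- pred[[m]]
      fold_scores <- as.data.frame(pred)
      if (length(models) > 1L) fold_scores$ensemble <- rowMeans(fold_scores)
      per_fold[[k]] <- vapply(fold_scores, function(s) auroc(y[!tr], s),
                              numeric(1))
    }
    cv <- as.data.frame(cv)
    if (length(models) > 1L) cv$ensemble <- rowMeans(cv)
    # refit on all labeled pairs to score the unlabeled candidates
    full_fits <- fit_ppi_models(Xall[ti, , drop = FALSE], y, models)
    full <- as.data.frame(predict_ppi_models(full_fits, Xall))
    if (length(models) > 1L) full$ensemble <- rowMeans(full)
  })
  scores <- data.frame(protein_a = features$protein_a,
                       protein_b = features$protein_b, full,
                       cv = FALSE, stringsAsFactors = FALSE)
  scores[ti, names(cv)] <- cv            # out-of-fold scores for labeled pairs
  scores$cv[ti] <- TRUE
  pooled <- vapply(names(cv), function(m) auroc(y, cv[[m]]), numeric(1))
  roc <- lapply(names(cv), function(m) roc_points(y, cv[[m]]))
  names(roc) <- names(cv)
  report <- list(models = names(cv), k_folds = k_folds, seed = as.integer(seed),
                 n_positive = sum(y == "positive"),
                 n_negative = sum(y == "negative"),
                 fold = fold,
                 per_fold_auroc = do.call(rbind, per_fold),
                 pooled_auroc = pooled,
                 roc = roc)
  list(scores = scores, report = report)
}

#' Select a PPI score threshold from a cross-validation ROC
#'
#' Rules: `"youden"` maximizes tpr - fpr on the pooled CV ROC;
#' `"fixed:<value>"` returns the literal value; `"fpr_at:<value>"` returns
#' the smallest cutoff whose fpr is at most the value. Cutoff ties are broken
#' toward the higher cutoff; infinite ROC end cutoffs are clamped to [0, 1].
#'
#' @param report a CV report from [train_and_score()].
#' @param rule rule string as above.
#' @param model which model's pooled ROC to use (default `"ensemble"`).
#' @return a scalar threshold in [0, 1].
#' @export
select_threshold <- function(report, rule = "youden", model = "ensemble") {
  if (grepl("^fixed:", rule))
    return(as.numeric(sub("^fixed:", "", rule)))
  roc <- report$roc[[model]]
  if (is.null(roc) || !nrow(roc)) stop("empty ROC for model ", model)
  cutoff <- pmin(pmax(roc$cutoff, 0), 1)
  if (rule == "youden") {
    j <- roc$tpr - roc$fpr
    best <- which(j == max(j))
    return(max(cutoff[best]))
  }
  if (grepl("^fpr_at:", rule)) {
    fmax <- as.numeric(sub("^fpr_at:", "", rule))
    ok <- roc$fpr <= fmax
    if (!any(ok)) stop("no cutoff achieves fpr <= ", fmax)
    return(min(cutoff[ok]))
  }
  stop("unknown threshold rule '", rule,
       "' (use youden, fixed:<v>, or fpr_at:<v>)")
}

#' Threshold a score table into a scored network
#'
#' @param scores score table from [train_and_score()].
#' @param threshold score cutoff; edges with `score >= threshold` retained.
#' @param model score column to use (default `"ensemble"`).
#' @param genotype,extract condition metadata for the network.
#' @return a [scored_network()].
#' @export
threshold_network <- function(scores, threshold, model = "ensemble",
                              genotype = "NA", extract = "NA") {
  scored_network(data.frame(protein_a = scores$protein_a,
                            protein_b = scores$protein_b,
                            score = scores[[model]],
                            stringsAsFactors = FALSE),
                 threshold = threshold, genotype = genotype, extract = extract)
}

#' Default forbidden subcompartment label pairs
#'
#' Outer membrane-matrix and intermembrane space-matrix contacts are
#' topologically implausible for a physical interaction and are vetoed.
#' @export
FORBIDDEN_COMPARTMENT_PAIRS <- list(c("OMM", "matrix"), c("IMS", "matrix"))

#' Remove biologically implausible edges from a scored network
#'
#' An edge whose endpoints carry a forbidden unordered subcompartment label
#' pair is removed; edges with one or both endpoints unannotated pass by
#' default and are counted as flagged.
#'
#' @param network a [scored_network()].
#' @param compartments named character vector protein -> label (e.g. from
#'   [read_compartments()]).
#' @param forbidden_pairs list of length-2 character vectors of forbidden
#'   unordered label pairs.
#' @return list with `network` (filtered), `removed` (data.frame of removed
#'   edges with a `reason` such as "OMM-matrix"), and
#'   `n_unannotated_passed`.
#' @export
filter_implausible <- function(network, compartments,
                               forbidden_pairs = FORBIDDEN_COMPARTMENT_PAIRS) {
  la <- unname(compartments[network$protein_a])
  lb <- unname(compartments[network$protein_b])
  forb_key <- vapply(forbidden_pairs, function(p)
    paste(sort(p), collapse = "-"), character(1))
  key <- ifelse(is.na(la) | is.na(lb), NA_character_,
                paste(pmin(la, lb), pmax(la, lb), sep = "-"))
  drop <- !is.na(key) & key %in% forb_key
  removed <- data.frame(protein_a = network$protein_a[drop],
                        protein_b = network$protein_b[drop],
                        score = network$score[drop],
                        reason = key[drop], stringsAsFactors = FALSE)
  kept <- as.data.frame(network)[!drop, , drop = FALSE]
  list(network = scored_network(kept, threshold = attr(network, "threshold"),
                                genotype = attr(network, "genotype"),
                                extract = attr(network, "extract")),
       removed = removed,
       n_unannotated_passed = sum((is.na(la) | is.na(lb)) & !drop))
}
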