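# Spot-level differential expression scoring: marker-based spot selection,
# per-gene group statistics, fold-change score (FCS) and signal-to-noise
# score (SNS), and the dual top-20% + P < 0.05 DEG call.

#' Construct a spot-expression object
#'
#' @param counts integer matrix, spots x genes, non-negative; spot ids as row
#'   names, gene ids as column names.
#' @param meta data.frame with one row per spot and columns `spot`, `region`,
#'   `group`, `soma_flag` (logical: the spot contains at least one complete
#'   neuron soma, supplied externally from imaging).
#' @param marker_genes declared marker gene list used by [select_spots()]
#'   (e.g. the dopaminergic markers Th / Slc6a3 (DAT) / Slc18a2 (VMAT2)).
#' @return an object of class `spot_expression`.
#' @export
spot_expression <- function(counts, meta, marker_genes = character()) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (any(counts < 0)) stop("counts must be non-negative")
  need <- c("spot", "region", "group", "soma_flag")
  if (!all(need %in% names(meta)))
    stop("meta must have columns ", paste(need, collapse = ", "))
  if (!identical(sort(rownames(counts)), sort(as.character(meta$spot))))
    stop("meta spots must match count matrix rows")
  if (anyDuplicated(meta$spot)) stop("duplicate spot ids in meta")
  meta <- meta[match(rownames(counts), meta$spot), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(counts = counts, meta = meta,
                 marker_genes = as.character(marker_genes)),
            class = "spot_expression")
}

#' @export
print.spot_expression <- function(x, ...) {
  cat(sprintf("spot_expression: %d spots x %d genes (%d markers declared)\n",
              nrow(x$counts), ncol(x$counts), length(x$marker_genes)))
  invisible(x)
}

#' Select analysis spots by region, soma presence, and marker expression
#'
#' A spot is retained when its region label matches, its `soma_flag` is true,
#' and every declared marker gene has a count of at least `marker_floor`.
#'
#' @param data a [spot_expression()].
#' @param region region label to keep.
#' @param marker_floor minimum count required for each marker (default 1;
#'   0 makes the marker criterion vacuous).
#' @return the filtered [spot_expression()]; rejects (with per-criterion
#'   attrition counts) when no spot survives.
#' @export
select_spots <- function(data, region, marker_floor = 1) {
  if (!region %in% data$meta$region)
    stop("region '", region, "' not present")
  missing_markers <- setdiff(data$marker_genes, colnames(data$counts))
  if (length(missing_markers))
    stop("marker gene(s) absent from counts: ",
         paste(missing_markers, collapse = ", "))
  in_region <- data$meta$region == region
  has_soma <- data$meta$soma_flag
  marker_ok <- if (length(data$marker_genes)) {
    apply(data$counts[, data$marker_genes, drop = FALSE] >= marker_floor,
          1L, all)
  } else rep(TRUE, nrow(data$counts))
  keep <- in_region & has_soma & marker_ok
  if (!any(keep))
    stop(sprintf(paste0("no spot survives selection (region kept %d of %d; ",
                        "soma kept %d; markers kept %d)"),
                 sum(in_region), length(keep), sum(in_region & has_soma),
                 sum(keep)))
  spot_expression(data$counts[keep, , drop = FALSE],
                  data$meta[keep, , drop = FALSE], data$marker_genes)
}

# counts-per-spot scaling to a fixed 10k total (so a global rescaling of the
# raw counts cancels exactly), then log2(x + 1)
normalize_spots <- function(counts, method = c("cp10k_log2", "none"),
                            target = 1e4) {
  method <- match.arg(method)
  if (method == "none") return(counts)
  totals <- rowSums(counts)
  scaled <- counts / ifelse(totals == 0, 1, totals) * target
  log2(scaled + 1)
}

#' Per-gene group means, standard deviations, and t-test P values
#'
#' Expression is normalized (counts-per-spot scaled to a fixed 10k total, then
#' log2(x + 1), unless `normalization = "none"`), and each gene is compared
#' between the two groups with a two-sided two-sample t test (Welch by
#' default; Student's pooled-variance variant available). Genes with zero
#' variance in both groups get P = 1 by convention.
#'
#' @param selected a [spot_expression()] after [select_spots()].
#' @param group_test,group_ref the two group labels; means are reported as
#'   `mu_test` / `mu_ref` (test vs reference, e.g. HOM vs WT).
#' @param normalization `"cp10k_log2"` or `"none"`.
#' @param test `"welch"` or `"student"`.
#' @return data.frame per gene: `gene`, `mu_test`, `mu_ref`, `sd_test`,
#'   `sd_ref`, `p`.
#' @export
gene_stats <- function(selected, group_test, group_ref,
                       normalization = "cp10k_log2", test = c("welch", "student")) {
  test <- match.arg(test)
  gi <- selected$meta$group == group_test
  gr <- selected$meta$group == group_ref
  if (sum(gi) < 2L || sum(gr) < 2L)
    stop("each group needs at least 2 spots (", group_test, ": ", sum(gi),
         ", ", group_ref, ": ", sum(gr), ")")
  X <- normalize_spots(selected$counts, normalization)
  A <- X[gi, , drop = FALSE]; B <- X[gr, , drop = FALSE]
  n1 <- nrow(A); n2 <- nrow(B)
  m1 <- colMeans(A); m2 <- colMeans(B)
  v1 <- apply(A, 2L, stats::var); v2 <- apply(B, 2L, stats::var)
  if (test == "welch") {
    se2 <- v1 / n1 + v2 / n2
    tstat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(tstat))
  }
  p <- 2 * stats::pt(-abs(tstat), df)
  p[v1 == 0 & v2 == 0] <- 1          # zero variance in both groups
  data.frame(gene = colnames(X), mu_test = m1, mu_ref = m2,
             sd_test = sqrt(v1), sd_ref = sqrt(v2), p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fold-change score (FCS) and signal-to-noise score (SNS) per gene
#'
#' `FCS = log2(mu_test / mu_ref) * (-log10 P)` and
#' `SNS = (mu_test - mu_ref) / (sd_test + sd_ref) * (-log10 P)`, where the
#' means/SDs come from [gene_stats()]. A pseudocount `eps` enters the ratio
#' when either mean is zero and the SD sum when it is zero, keeping both
#' scores finite. P values are floored at `p_floor` so that -log10 P is
#' finite for vanishingly small P.
#'
#' @param stats data.frame from [gene_stats()].
#' @param eps pseudocount (default 1).
#' @param p_floor smallest usable P (default 1e-300).
#' @return a `deg_score_table` data.frame: the input columns plus `fcs`,
#'   `sns`.
#' @export
score_genes <- function(stats, eps = 1, p_floor = 1e-300) {
  p <- pmax(stats$p, p_floor)
  nlp <- -log10(p)
  mt <- stats$mu_test; mr <- stats$mu_ref
  zero <- mt == 0 | mr == 0
  ratio <- ifelse(zero, (mt + eps) / (mr + eps), mt / mr)
  ssum <- stats$sd_test + stats$sd_ref
  ssum <- ifelse(ssum == 0, ssum + eps, ssum)
  out <- stats
  out$fcs <- log2(ratio) * nlp
  out$sns <- (mt - mr) / ssum * nlp
  structure(out, class = c("deg_score_table", "data.frame"), eps = eps)
}

dense_rank_desc <- function(x) match(x, sort(unique(x), decreasing = TRUE))

#' Call differentially expressed genes by the dual top-20% rule
#'
#' A gene is flagged when its t-test P is below `p_cut` and it ranks within
#' the top `top_frac` of genes by both scoring metrics (|FCS| and |SNS| by
#' default; signed scores with `absolute = FALSE`). Ranks are dense (ties
#' share a rank) and the cutoff is `ceiling(top_frac * N)` ranks.
#'
#' @param table a `deg_score_table` from [score_genes()].
#' @param p_cut P-value cutoff (default 0.05).
#' @param top_frac top fraction per metric (default 0.20).
#' @param absolute rank absolute scores (default) or signed scores.
#' @return the table with added `rank_fcs`, `rank_sns`, `deg_flag` columns;
#'   flagged genes are the DEG calls.
#' @export
call_degs <- function(table, p_cut = 0.05, top_frac = 0.20, absolute = TRUE) {
  if (!nrow(table)) stop("empty score table")
  f <- if (absolute) abs(table$fcs) else table$fcs
  s <- if (absolute) abs(table$sns) else table$sns
  table$rank_fcs <- dense_rank_desc(f)
  table$rank_sns <- dense_rank_desc(s)
  cutoff <- ceiling(top_frac * nrow(table))
  table$deg_flag <- table$p < p_cut & table$rank_fcs <= cutoff &
    table$rank_sns <= cutoff
  table
}
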