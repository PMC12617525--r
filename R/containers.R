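# Core S3 containers shared across the pipeline stages.

#' Construct an elution matrix
#'
#' An elution matrix is the pipeline's primary input: a protein x fraction
#' table of non-negative abundances (spectral counts or averaged log2
#' intensities) for one (genotype, extract, engine) condition. It is stored as
#' a base numeric matrix with protein identifiers as row names, fraction
#' labels as column names, and condition metadata in attributes.
#'
#' @param values numeric matrix; rows are proteins, columns fractions. Row
#'   names are required and must be unique. `NA` marks an explicitly missing
#'   cell (resolved by [impute_zeros()]); all non-missing values must be
#'   non-negative.
#' @param genotype,extract,engine condition metadata labels. `extract` is
#'   conventionally `"WTL"` (whole tissue lysate) or `"Mt"` (mitochondrial).
#' @return an object of class `elution_matrix`.
#' @examples
#' m <- elution_matrix(matrix(1:6, 2, 3, dimnames = list(c("A", "B"), NULL)),
#'                     genotype = "WT", extract = "Mt", engine = "eng1")
#' dim(m)
#' @export
elution_matrix <- function(values, genotype = "NA", extract = "NA",
                           engine = "NA") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)))
    stop("elution matrix requires protein identifiers as row names")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicate protein identifier(s): ", paste(unique(dup), collapse = ", "))
  if (any(values < 0, na.rm = TRUE))
    stop("elution matrix values must be non-negative")
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("fraction_%03d", seq_len(ncol(values)))
  structure(values, class = c("elution_matrix", class(matrix())),
            genotype = genotype, extract = extract, engine = engine)
}

#' @export
print.elution_matrix <- function(x, ...) {
  cat(sprintf("elution_matrix: %d proteins x %d fractions [genotype=%s extract=%s engine=%s]\n",
              nrow(x), ncol(x), attr(x, "genotype"), attr(x, "extract"),
              attr(x, "engine")))
  invisible(x)
}

# subsetting keeps class + metadata (matrix subsetting would drop them)
#' @export
`[.elution_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, class = class(x), genotype = attr(x, "genotype"),
                     extract = attr(x, "extract"), engine = attr(x, "engine"))
  out
}

#' Construct a complex catalog
#'
#' A catalog of named protein sets: either a reference standard (CORUM-style),
#' complexes predicted by [detect_complexes()], or planted ground truth from
#' the synthetic-data generator. Doubles as classifier training standard and
#' clustering evaluation target.
#'
#' @param entries named list of character vectors (complex id -> member set).
#'   Ids must be unique and member sets non-empty; duplicate members within a
#'   set are collapsed.
#' @param source one of `"reference"`, `"predicted"`, `"planted"`.
#' @return an object of class `complex_catalog` (a named list).
#' @export
complex_catalog <- function(entries, source = c("reference", "predicted", "planted")) {
  source <- match.arg(source)
  if (is.null(names(entries)) && length(entries))
    stop("complex catalog entries must be named")
  dup <- names(entries)[duplicated(names(entries))]
  if (length(dup))
    stop("duplicate complex id(s): ", paste(unique(dup), collapse = ", "))
  entries <- lapply(entries, function(m) unique(as.character(m)))
  if (any(!lengths(entries)))
    stop("complex member sets must be non-empty")
  structure(entries, class = "complex_catalog", source = source)
}

#' @export
print.complex_catalog <- function(x, ...) {
  cat(sprintf("complex_catalog (%s): %d complexes, %d distinct proteins\n",
              attr(x, "source"), length(x), length(unique(unlist(x)))))
  invisible(x)
}

#' All unordered intra-complex protein pairs of a catalog
#'
#' Pairs are returned in canonical form (endpoint `a` lexicographically before
#' `b`) with one row per distinct pair, regardless of how many complexes
#' contain it.
#'
#' @param catalog a [complex_catalog()].
#' @param min_size skip complexes smaller than this.
#' @return data.frame with columns `protein_a`, `protein_b`.
#' @export
catalog_pairs <- function(catalog, min_size = 2L) {
  sets <- Filter(function(m) length(m) >= min_size, catalog)
  if (!length(sets))
    return(data.frame(protein_a = character(), protein_b = character(),
                      stringsAsFactors = FALSE))
  pairs <- do.call(rbind, lapply(sets, function(m) t(utils::combn(sort(m), 2L))))
  pairs <- unique(data.frame(protein_a = pairs[, 1], protein_b = pairs[, 2],
                             stringsAsFactors = FALSE))
  rownames(pairs) <- NULL
  pairs
}

#' Construct a scored PPI network
#'
#' A weighted undirected protein-protein interaction network for one
#' (genotype, extract) condition. Edges are stored in canonical form
#' (`protein_a` lexicographically before `protein_b`, each unordered pair at
#' most once, no self-loops) with scores in [0, 1]. When a threshold is given,
#' only edges with `score >= threshold` are retained.
#'
#' @param edges data.frame with columns `protein_a`, `protein_b`, `score`.
#' @param threshold score cutoff already applied (edges below it are dropped).
#' @param genotype,extract condition metadata labels.
#' @return an object of class `scored_network`.
#' @export
scored_network <- function(edges, threshold = 0, genotype = "NA", extract = "NA") {
  stopifnot(all(c("protein_a", "protein_b", "score") %in% names(edges)))
  a <- as.character(edges$protein_a); b <- as.character(edges$protein_b)
  if (any(a == b)) stop("self-loops are not allowed in a scored network")
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(protein_a = a, protein_b = b,
                    score = as.numeric(edges$score), stringsAsFactors = FALSE)
  if (anyDuplicated(paste(out$protein_a, out$protein_b)))
    stop("duplicate edges in scored network")
  if (any(out$score < 0 | out$score > 1))
    stop("edge scores must lie in [0, 1]")
  out <- out[out$score >= threshold, , drop = FALSE]
  out <- out[order(out$protein_a, out$protein_b), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("scored_network", "data.frame"),
            threshold = threshold, genotype = genotype, extract = extract)
}

#' @export
print.scored_network <- function(x, ...) {
  cat(sprintf("scored_network: %d edges, %d proteins [genotype=%s extract=%s threshold=%g]\n",
              nrow(x), length(network_proteins(x)), attr(x, "genotype"),
              attr(x, "extract"), attr(x, "threshold")))
  invisible(x)
}

#' Proteins incident to at least one edge of a network
#' @param network a [scored_network()].
#' @return character vector, sorted.
#' @export
network_proteins <- function(network)
  sort(unique(c(network$protein_a, network$protein_b)))

# canonical "a|b" edge keys, used wherever edge sets are compared
edge_keys <- function(network) paste(network$protein_a, network$protein_b, sep = "|")

# run `expr` under `seed` without touching the caller's RNG stream
local_seed <- function(seed, expr) withr::with_seed(as.integer(seed), expr)

# derive a named sub-seed (< 2^31) from a master seed, so independent stages
# never share an RNG stream
derive_seed <- function(seed, what) {
  h <- sum(utf8ToInt(what) * seq_along(utf8ToInt(what)))
  (as.integer(seed) * 7919L + as.integer(h %% 104729)) %% 2147483629L
}
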