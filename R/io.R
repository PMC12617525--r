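# Readers/writers for every on-disk artifact. All writers emit a stable row
# and column order so outputs are diffable; all readers reject malformed
# input rather than coercing it.

#' Read an elution matrix from TSV
#'
#' Expects a header row of fraction labels with the first column holding
#' protein identifiers. Empty cells and the literal string `NA` both map to
#' explicit missing (both dialects occur in exported MS tables). If a JSON
#' metadata sidecar written by [write_matrix()] sits next to the file it is
#' read back; explicit `genotype`/`extract`/`engine` arguments override it.
#'
#' @param path TSV file path.
#' @param genotype,extract,engine optional metadata overrides.
#' @return an [elution_matrix()].
#' @export
read_matrix <- function(path, genotype = NULL, extract = NULL, engine = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("no proteins in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  body <- fields[-1L]
  nfield <- length(header)
  ragged <- which(lengths(body) != nfield)
  if (length(ragged))
    stop("ragged row at line ", ragged[1L] + 1L, " in ", path,
         " (expected ", nfield, " fields, got ", lengths(body)[ragged[1L]], ")")
  ids <- vapply(body, `[[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate protein identifier(s) in ", path, ": ",
         paste(dup, collapse = ", "))
  vals <- vapply(body, function(f) {
    v <- f[-1L]
    v[v == "" | v == "NA"] <- NA_character_
    suppressWarnings(as.numeric(v))
  }, numeric(nfield - 1L))
  vals <- t(matrix(vals, nrow = nfield - 1L))
  if (any(is.nan(vals))) stop("non-numeric abundance value in ", path)
  if (any(vals < 0, na.rm = TRUE))
    stop("negative abundance value in ", path)
  dimnames(vals) <- list(ids, header[-1L])
  meta <- list(genotype = "NA", extract = "NA", engine = "NA")
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar))
    meta <- utils::modifyList(meta, jsonlite::read_json(sidecar, simplifyVector = TRUE))
  if (!is.null(genotype)) meta$genotype <- genotype
  if (!is.null(extract))  meta$extract  <- extract
  if (!is.null(engine))   meta$engine   <- engine
  elution_matrix(vals, meta$genotype, meta$extract, meta$engine)
}

#' Write an elution matrix as TSV (with a JSON metadata sidecar)
#'
#' @param matrix an [elution_matrix()].
#' @param path output TSV path; metadata goes to `<path>.meta.json`.
#' @param digits significant digits for abundance formatting.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path, digits = 6L) {
  vals <- unclass(matrix)
  rows <- apply(vals, 1L, function(v)
    paste(ifelse(is.na(v), "NA", format_num(v, digits)), collapse = "\t"))
  writeLines(c(paste(c("protein", colnames(vals)), collapse = "\t"),
               paste(rownames(vals), rows, sep = "\t")), path)
  jsonlite::write_json(
    list(genotype = attr(matrix, "genotype"), extract = attr(matrix, "extract"),
         engine = attr(matrix, "engine")),
    paste0(path, ".meta.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# fixed-precision numeric formatting shared by all writers (diffable output)
format_num <- function(x, digits = 6L) {
  out <- formatC(signif(x, digits), digits = digits, format = "g")
  gsub(" ", "", out)
}

#' Read a complex catalog from a GMT file
#'
#' GMT dialect: one set per line, `name TAB description TAB member...`.
#'
#' @param path GMT file path.
#' @param source catalog provenance label, see [complex_catalog()].
#' @return a [complex_catalog()].
#' @export
read_gmt <- function(path, source = "reference") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("GMT line ", short[1L], " in ", path,
         " has fewer than 3 fields (name, description, members...)")
  ids <- vapply(fields, `[[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate complex name(s) in ", path, ": ", paste(dup, collapse = ", "))
  entries <- lapply(fields, function(f) f[-(1:2)])
  names(entries) <- ids
  complex_catalog(entries, source = source)
}

#' Write a complex catalog as a GMT file
#'
#' Complexes are written in sorted id order and members in sorted order, so
#' the output is deterministic.
#'
#' @param catalog a [complex_catalog()].
#' @param path output path.
#' @param description description field (recycled), default the source label.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(catalog, path, description = NULL) {
  if (is.null(description)) description <- attr(catalog, "source")
  ids <- sort(names(catalog))
  writeLines(vapply(ids, function(id)
    paste(c(id, description, sort(catalog[[id]])), collapse = "\t"),
    character(1)), path)
  invisible(path)
}

#' Vocabulary of mitochondrial subcompartment labels
#'
#' `OMM` outer membrane, `IMS` intermembrane space, `matrix`,
#' `inner_membrane`, plus `non_mito` for proteins outside the organelle.
#' @export
COMPARTMENT_LABELS <- c("OMM", "IMS", "matrix", "inner_membrane", "non_mito")

#' Read a protein -> subcompartment annotation table
#'
#' Two-column TSV (protein, label). Labels must come from `vocabulary`;
#' a protein listed twice with conflicting labels is rejected.
#'
#' @param path TSV path (no header).
#' @param vocabulary allowed labels, default [COMPARTMENT_LABELS].
#' @return named character vector protein -> label.
#' @export
read_compartments <- function(path, vocabulary = COMPARTMENT_LABELS) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "")
  if (ncol(tab) != 2L) stop("compartment table must have exactly 2 columns")
  bad <- setdiff(unique(tab[[2L]]), vocabulary)
  if (length(bad))
    stop("unknown compartment label(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(vocabulary, collapse = ", "), ")")
  conflict <- unique(tab[[1L]][duplicated(tab[[1L]])])
  for (p in conflict)
    if (length(unique(tab[[2L]][tab[[1L]] == p])) > 1L)
      stop("protein ", p, " listed with conflicting compartment labels")
  out <- tab[[2L]][!duplicated(tab[[1L]])]
  names(out) <- tab[[1L]][!duplicated(tab[[1L]])]
  out
}

#' Write a compartment annotation table
#' @param compartments named character vector protein -> label.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_compartments <- function(compartments, path) {
  ids <- sort(names(compartments))
  writeLines(paste(ids, compartments[ids], sep = "\t"), path)
  invisible(path)
}

#' Write a scored network as an edge-list TSV
#'
#' Canonical 4-column form: `protein_a`, `protein_b` (lexicographically
#' ordered endpoints), `score`, `kept` flag -- prevents duplicate undirected
#' edges and keeps removed (e.g. compartment-implausible) edges auditable.
#'
#' @param network a [scored_network()].
#' @param path output TSV path.
#' @param removed optional data.frame of removed edges (same columns plus
#'   `reason`), written with `kept = FALSE`.
#' @return `path`, invisibly.
#' @export
write_edges <- function(network, path, removed = NULL) {
  kept <- data.frame(protein_a = network$protein_a, protein_b = network$protein_b,
                     score = format_num(network$score), kept = "TRUE",
                     stringsAsFactors = FALSE)
  if (!is.null(removed) && nrow(removed))
    kept <- rbind(kept, data.frame(protein_a = removed$protein_a,
                                   protein_b = removed$protein_b,
                                   score = format_num(removed$score),
                                   kept = "FALSE", stringsAsFactors = FALSE))
  kept <- kept[order(kept$protein_a, kept$protein_b), , drop = FALSE]
  lines <- c("protein_a\tprotein_b\tscore\tkept",
             do.call(paste, c(kept, sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a scored network from an edge-list TSV
#' @param path TSV written by [write_edges()].
#' @param threshold,genotype,extract metadata to attach.
#' @return a [scored_network()] of the `kept = TRUE` edges.
#' @export
read_edges <- function(path, threshold = 0, genotype = "NA", extract = "NA") {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "character", "numeric",
                                          "logical"))
  scored_network(tab[tab$kept, c("protein_a", "protein_b", "score")],
                 threshold = threshold, genotype = genotype, extract = extract)
}

#' Write an analysis report as JSON
#'
#' All structured reports (preprocessing, CV, intersections, lost-PPI
#' attribution, enrichment, manifests) share this envelope with a schema
#' version field.
#'
#' @param report a named list.
#' @param path output path.
#' @param schema short schema name embedded in the envelope.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, schema = "cofracnet-report") {
  jsonlite::write_json(c(list(schema = schema, schema_version = 1L), report),
                       path, auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
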