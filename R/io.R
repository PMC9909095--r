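# Readers, writers and validators for the tabular and tree formats the
# pipeline touches. All downstream operations consume the validated objects
# returned here; no analysis function reads files itself.

#' Validate a taxon-by-sample count matrix
#'
#' @param counts numeric matrix, taxa in rows, samples in columns, with
#'   unique row and column names and non-negative integer entries.
#' @param require_nonzero require at least one non-zero count per sample.
#' @return The validated matrix (in storage mode integer), invisibly usable.
#' @export
validate_counts <- function(counts, require_nonzero = TRUE) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("counts must be a numeric matrix (taxa x samples)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have taxon row names and sample column names")
  if (anyDuplicated(rownames(counts))) stop("duplicate taxon identifiers")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample identifiers")
  if (anyNA(counts)) stop("counts contain missing values")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  if (require_nonzero && any(colSums(counts) == 0))
    stop("every sample must have at least one non-zero count")
  storage.mode(counts) <- "integer"
  counts
}

#' Read a taxon-by-sample count table from TSV
#'
#' Expects a QIIME-style feature table: a header row of sample identifiers
#' (the first header cell is ignored), one row per taxon with the taxon
#' identifier in the first column and integer counts in the remaining cells.
#'
#' @param path path to a tab-separated file.
#' @return Integer matrix, taxa x samples.
#' @export
read_count_table <- function(path) {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  if (ncol(raw) < 2) stop("count table needs a taxon column and >= 1 sample")
  taxa <- raw[[1]]
  samples <- colnames(raw)[-1]  # taken before subsetting: `[.data.frame`
  mat <- as.matrix(raw[, -1, drop = FALSE])  # would mangle duplicate names
  if (any(mat == "" | is.na(mat))) stop("blank cells in count table")
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat)))
  if (anyNA(num)) stop("non-numeric cells in count table")
  dimnames(num) <- list(taxa, samples)
  validate_counts(num, require_nonzero = FALSE)
}

#' Write a count table as TSV
#'
#' @param counts validated count matrix.
#' @param path output path.
#' @export
write_count_table <- function(counts, path) {
  counts <- validate_counts(counts, require_nonzero = FALSE)
  df <- data.frame(taxon = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny with branch lengths from a Newick file
#'
#' @param path path to a single-tree Newick file.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path), error = function(e)
    stop("failed to parse Newick file: ", conditionMessage(e)))
  if (is.null(tree)) stop("failed to parse Newick file")
  if (inherits(tree, "multiPhylo")) stop("expected a single tree")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  tree
}

#' Write a phylogeny to a Newick file
#' @param tree an [ape::phylo] object.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

.SAMPLE_COLS <- c("sample", "station", "depth_layer", "latitude", "longitude")
.ENV_COLS <- c("temperature", "salinity", "dissolved_oxygen",
               "chlorophyll_a", "tin", "dip", "silicate")

#' Validate a sample metadata frame
#'
#' Required columns: `sample`, `station`, `depth_layer`, `latitude`,
#' `longitude` and the environmental variables `temperature`, `salinity`,
#' `dissolved_oxygen`, `chlorophyll_a`, `tin`, `dip`, `silicate`.
#'
#' @param frame a data frame of per-sample metadata.
#' @param layers admissible depth-layer labels.
#' @return The validated data frame.
#' @export
validate_sample_frame <- function(frame, layers = depth_layers()) {
  need <- c(.SAMPLE_COLS, .ENV_COLS)
  miss <- setdiff(need, names(frame))
  if (length(miss)) stop("missing metadata columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(frame$sample)) stop("duplicate sample identifiers")
  if (any(frame$latitude < -90 | frame$latitude > 90)) stop("latitude out of [-90, 90]")
  if (any(frame$longitude < -180 | frame$longitude > 180)) stop("longitude out of [-180, 180]")
  bad <- setdiff(unique(frame$depth_layer), layers)
  if (length(bad)) stop("unknown depth layer(s): ", paste(bad, collapse = ", "))
  frame$depth_layer <- factor(frame$depth_layer, levels = layers)
  frame
}

#' Read sample metadata from TSV
#' @param path path to a tab-separated metadata file.
#' @param layers admissible depth-layer labels.
#' @return Validated data frame of per-sample metadata.
#' @export
read_sample_frame <- function(path, layers = depth_layers()) {
  validate_sample_frame(read.delim(path, sep = "\t", check.names = FALSE), layers)
}

#' Read a taxonomy map from TSV
#'
#' @param path TSV with columns `taxon`, `phylum`, `class`, `order` (a
#'   `guild` column, e.g. bacteria vs microeukaryote, is kept if present).
#' @return Data frame keyed by taxon.
#' @export
read_taxonomy <- function(path) {
  tax <- read.delim(path, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  need <- c("taxon", "phylum", "class", "order")
  miss <- setdiff(need, names(tax))
  if (length(miss)) stop("missing taxonomy columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(tax$taxon)) stop("duplicate taxa in taxonomy")
  if (any(tax$order == "" | is.na(tax$order))) stop("empty order labels")
  tax
}

#' Run configuration
#'
#' Bundles the tunable parameters shared across pipeline stages.
#'
#' @param seed master random seed.
#' @param n_null number of null-model randomisations (default 999).
#' @param rho_threshold absolute Spearman correlation needed for a network
#'   edge (default 0.4).
#' @param alpha p-value gate for network edges (default 0.05).
#' @param rarefaction_depth reads per sample after rarefaction (default
#'   16704).
#' @param n_pcnm number of spatial eigenfunctions carried into the driver
#'   analyses (default 5).
#' @param paths named list of input file paths (optional).
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_null = 999L, rho_threshold = 0.4,
                       alpha = 0.05, rarefaction_depth = 16704L,
                       n_pcnm = 5L, paths = list()) {
  if (n_null < 1) stop("n_null must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (rho_threshold <= 0 || rho_threshold >= 1) stop("rho_threshold must be in (0, 1)")
  if (rarefaction_depth < 1) stop("rarefaction_depth must be >= 1")
  structure(list(seed = as.integer(seed), n_null = as.integer(n_null),
                 rho_threshold = rho_threshold, alpha = alpha,
                 rarefaction_depth = as.integer(rarefaction_depth),
                 n_pcnm = as.integer(n_pcnm), paths = paths),
            class = "run_config")
}

#' Write result tables plus a JSON run manifest
#'
#' Each element of `tables` is written as `<name>.tsv` under `dir`; the run
#' configuration, seed and file listing go to `manifest.json`.
#'
#' @param tables named list of data frames (or matrices with dimnames).
#' @param dir output directory (created if needed).
#' @param config a [run_config()] object.
#' @param warnings character vector of warnings to record.
#' @return Invisibly, the manifest as a list.
#' @export
write_results <- function(tables, dir, config = run_config(), warnings = character()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stopifnot(!is.null(names(tables)), all(nzchar(names(tables))))
  files <- character()
  for (nm in names(tables)) {
    x <- tables[[nm]]
    if (is.matrix(x)) x <- data.frame(id = rownames(x), x, check.names = FALSE)
    f <- file.path(dir, paste0(nm, ".tsv"))
    write.table(x, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, basename(f))
  }
  manifest <- list(config = unclass(config)[setdiff(names(config), "paths")],
                   paths = config$paths, files = files, warnings = warnings)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Re-read a run manifest
#' @param path path to `manifest.json`.
#' @return The manifest list; `$config` is restored as a `run_config`.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$config <- do.call(run_config, c(m$config, list(paths = as.list(m$paths))))
  m
}
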