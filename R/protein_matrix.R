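#' Canonical niche labels
#'
#' The five hallmark glioblastoma histomorphologic niches in their fixed
#' canonical order: leading edge (LE), infiltrating tumor (IT), cellular
#' tumor (CT), microvascular proliferation (MVP), and pseudopalisading
#' cells around necrosis (PAN). All niche factors, probability vectors and
#' tie-breaks in the package use this order.
#'
#' @format Character vector of length five.
#' @export
NICHE_LEVELS <- c("LE", "IT", "CT", "MVP", "PAN")

#' Transcriptional subtype labels used for bulk cohorts
#' @format Character vector of length five.
#' @export
SUBTYPE_LEVELS <- c("proneural", "classical", "mesenchymal", "IDH-mutant", "normal")

.SCALE_TAGS <- c("raw", "log2", "log2-imputed", "zscored")

#' Construct a protein abundance matrix
#'
#' A `protein_matrix` holds a protein x sample abundance matrix (missing
#' entries allowed), per-sample metadata, and a `scale_tag` recording where
#' the matrix sits in the preprocessing pipeline. The tag may only move
#' forward along raw -> log2 -> log2-imputed -> zscored, which is how the
#' pipeline order (filter, transform, impute, z-score) is enforced.
#'
#' @param values numeric matrix, proteins as rows (rownames = gene symbols),
#'   samples as columns (colnames = unique sample ids). `NA` marks missing.
#' @param sample_meta data.frame with one row per sample; must contain a
#'   `sample_id` column matching `colnames(values)`. Typical extra columns:
#'   `patient`, `group` (niche or subtype), `platform`.
#' @param scale_tag one of `"raw"`, `"log2"`, `"log2-imputed"`, `"zscored"`.
#' @return An object of class `protein_matrix`.
#' @export
protein_matrix <- function(values, sample_meta = NULL, scale_tag = "raw") {
  stopifnot(is.matrix(values), is.numeric(values))
  scale_tag <- match.arg(scale_tag, .SCALE_TAGS)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have protein rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate protein_ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))])[1:3], collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample_ids")
  if (is.null(sample_meta)) {
    sample_meta <- data.frame(sample_id = colnames(values), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(sample_meta), "sample_id" %in% names(sample_meta))
  if (!setequal(sample_meta$sample_id, colnames(values)) ||
      nrow(sample_meta) != ncol(values))
    stop("sample_meta$sample_id must match colnames(values) one-to-one")
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), , drop = FALSE]
  rownames(sample_meta) <- NULL
  structure(list(values = values, sample_meta = sample_meta, scale_tag = scale_tag),
            class = "protein_matrix")
}

#' @export
print.protein_matrix <- function(x, ...) {
  cat(sprintf("protein_matrix: %d proteins x %d samples [%s], %d missing (%.1f%%)\n",
              nrow(x$values), ncol(x$values), x$scale_tag,
              sum(is.na(x$values)),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.protein_matrix <- function(x) dim(x$values)

protein_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

# forward-only scale_tag transition guard
advance_scale <- function(x, from, to) {
  if (!x$scale_tag %in% from)
    stop(sprintf("matrix has scale_tag '%s'; this step requires %s",
                 x$scale_tag, paste(sQuote(from), collapse = " or ")))
  x$scale_tag <- to
  x
}

subset_proteins <- function(x, ids) {
  x$values <- x$values[ids, , drop = FALSE]
  x
}

#' Subset a protein matrix to named samples
#'
#' Keeps the requested sample columns (in the requested order) together with
#' their metadata rows; used e.g. to split a matrix along a
#' [stratified_split()].
#'
#' @param x a [protein_matrix()].
#' @param ids character vector of sample ids (or a logical/integer index).
#' @return The subset [protein_matrix()].
#' @export
subset_samples <- function(x, ids) {
  stopifnot(inherits(x, "protein_matrix"))
  x$values <- x$values[, ids, drop = FALSE]
  x$sample_meta <- x$sample_meta[match(colnames(x$values), x$sample_meta$sample_id), ,
                                 drop = FALSE]
  rownames(x$sample_meta) <- NULL
  x
}

#' Write a protein matrix as TSV
#'
#' Proteins as rows, first column `gene_symbol`, one column per sample,
#' missing values written as empty cells. Sample metadata goes to a sibling
#' file `<path>.meta.tsv` unless `meta_path` is given.
#'
#' @param x a [protein_matrix()].
#' @param path output TSV path.
#' @param meta_path optional metadata TSV path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path, meta_path = paste0(path, ".meta.tsv")) {
  df <- data.frame(gene_symbol = protein_ids(x), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  meta <- x$sample_meta
  meta$scale_tag <- x$scale_tag
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a protein matrix from TSV
#'
#' @param path TSV written by [write_matrix_tsv()] (or any matrix with a
#'   gene-symbol first column and sample columns; empty cells = missing).
#' @param meta_path optional metadata TSV; defaults to `<path>.meta.tsv`
#'   when that file exists.
#' @param scale_tag scale of the stored values; if `NULL`, taken from the
#'   metadata file, else defaults to `"raw"`. Never guessed from the data.
#' @return A [protein_matrix()].
#' @export
read_matrix_tsv <- function(path, meta_path = NULL, scale_tag = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          na.strings = c("", "NA"), stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- ids
  if (is.null(meta_path) && file.exists(paste0(path, ".meta.tsv")))
    meta_path <- paste0(path, ".meta.tsv")
  meta <- NULL
  if (!is.null(meta_path)) {
    meta <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE, quote = "", comment.char = "")
    if (is.null(scale_tag) && "scale_tag" %in% names(meta))
      scale_tag <- meta$scale_tag[1]
    meta$scale_tag <- NULL
  }
  if (is.null(scale_tag)) scale_tag <- "raw"
  protein_matrix(vals, meta, scale_tag = scale_tag)
}

#' Write a protein matrix in GCT 1.2 format
#'
#' @param x a [protein_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_gct <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(x$values), ncol(x$values), sep = "\t")), con)
  df <- data.frame(NAME = protein_ids(x), Description = "na", x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a GCT 1.2 matrix
#'
#' @param path GCT path; the `#1.2` header and the dimensions line are
#'   validated against the table body.
#' @param scale_tag scale of the stored values (default `"raw"`).
#' @return A [protein_matrix()].
#' @export
read_matrix_gct <- function(path, scale_tag = "raw") {
  hdr <- readLines(path, n = 2)
  if (length(hdr) < 2 || trimws(hdr[1]) != "#1.2")
    stop("not a GCT 1.2 file: ", path)
  dims <- as.integer(strsplit(hdr[2], "\t")[[1]][1:2])
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 2,
                          check.names = FALSE, na.strings = c("", "NA"),
                          stringsAsFactors = FALSE, quote = "", comment.char = "")
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(vals) <- "double"
  rownames(vals) <- as.character(df[[1]])
  if (!identical(dim(vals), dims))
    stop(sprintf("GCT dims line says %d x %d but body is %d x %d",
                 dims[1], dims[2], nrow(vals), ncol(vals)))
  protein_matrix(vals, NULL, scale_tag = scale_tag)
}
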