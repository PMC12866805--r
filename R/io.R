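# Plain-text interchange: TSV for tables, Matrix Market + sidecar TSVs for
# counts, GMT for gene sets, JSON for truth/reports.

#' Write a quant table to TSV (plus channel-group sidecar)
#'
#' The main TSV has `protein_id` first, then one column per channel; the
#' sidecar is a two-column TSV `channel`, `group`.
#'
#' @param table A [quant_table()].
#' @param path Output TSV path.
#' @param groups_path Sidecar path; default `<path>` with a `.groups.tsv`
#'   suffix.
#' @return `path`, invisibly.
#' @export
write_quant_tsv <- function(table, path,
                            groups_path = sub("\\.tsv$", ".groups.tsv", path)) {
  .check(inherits(table, "quant_table"), "table must be a quant_table")
  df <- data.frame(protein_id = table$protein_ids, table$intensities,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(channel = names(table$channel_groups),
               group = unname(table$channel_groups)),
    groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a quant table from TSV (plus channel-group sidecar)
#'
#' Proteins with any missing or non-positive intensity are dropped with a
#' message reporting the count (no imputation).
#'
#' @param path Main TSV path (first column `protein_id`).
#' @param groups_path Two-column sidecar TSV (`channel`, `group`); groups
#'   may be `probe`/`competition` or the assay-style aliases
#'   `CDDP-P`/`Comp`.
#' @return A [quant_table()].
#' @export
read_quant_tsv <- function(path, groups_path = sub("\\.tsv$", ".groups.tsv", path)) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  .check("protein_id" %in% names(df), "first column must be protein_id")
  g <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  .check(all(c("channel", "group") %in% names(g)),
         "groups sidecar needs columns channel, group")
  alias <- c("probe" = "probe", "competition" = "competition",
             "CDDP-P" = "probe", "Comp" = "competition")
  .check(all(g$group %in% names(alias)),
         "unknown channel group label(s): ",
         paste(setdiff(g$group, names(alias)), collapse = ", "))
  m <- as.matrix(df[, g$channel, drop = FALSE])
  ok <- apply(m, 1, function(r) all(is.finite(r) & r > 0))
  if (any(!ok))
    message(sum(!ok), " protein(s) dropped for missing or non-positive intensities")
  quant_table(m[ok, , drop = FALSE],
              stats::setNames(unname(alias[g$group]), g$channel),
              df$protein_id[ok])
}

#' Write labeled counts as Matrix Market plus sidecar TSVs
#'
#' Writes `matrix.mtx`, `genes.tsv`, `barcodes.tsv`, `celltypes.tsv`
#' into `dir`.
#'
#' @param counts A [labeled_counts()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(counts, dir) {
  .check(inherits(counts, "labeled_counts"), "counts must be labeled_counts")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- counts$counts
  if (!inherits(m, "sparseMatrix")) m <- methods::as(m, "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(counts$gene_ids, file.path(dir, "genes.tsv"))
  barcodes <- colnames(counts$counts) %||%
    sprintf("cell%05d", seq_len(ncol(counts$counts)))
  writeLines(barcodes, file.path(dir, "barcodes.tsv"))
  writeLines(counts$cell_labels, file.path(dir, "celltypes.tsv"))
  invisible(dir)
}

#' Read labeled counts from a Matrix Market directory
#'
#' Expects `matrix.mtx`, `genes.tsv`, `barcodes.tsv`, `celltypes.tsv`
#' as written by [write_counts_mtx()].
#'
#' @param dir Input directory.
#' @return A [labeled_counts()].
#' @export
read_counts_mtx <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                   "CsparseMatrix")
  genes <- readLines(file.path(dir, "genes.tsv"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  labels <- readLines(file.path(dir, "celltypes.tsv"))
  .check(length(genes) == nrow(m), "genes.tsv length must match matrix rows")
  .check(length(barcodes) == ncol(m) && length(labels) == ncol(m),
         "barcodes/celltypes length must match matrix columns")
  colnames(m) <- barcodes
  labeled_counts(m, labels, genes)
}

#' Write a data.frame as TSV
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
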