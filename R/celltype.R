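# Cell-type integration: project called targets onto a cell-type-labeled
# scRNA-seq matrix.  Expression is library-size normalized and log1p
# transformed per cell, averaged within each cell type, row-scaled across
# cell types, and each target is assigned to the type holding its strict
# row maximum ("highest scaled value").

AMBIGUOUS <- "AMBIGUOUS"

#' Construct a labeled single-cell count matrix
#'
#' @param counts Gene x cell matrix of non-negative integer counts; dense
#'   or a `Matrix` sparse matrix.  Row names are gene ids if `gene_ids` is
#'   missing.
#' @param cell_labels Character vector, one cell-type label per cell
#'   (column).
#' @param gene_ids Optional character vector of unique gene ids.
#' @return A `labeled_counts` object.
#' @export
labeled_counts <- function(counts, cell_labels, gene_ids = rownames(counts)) {
  .check(length(dim(counts)) == 2L, "counts must be a gene x cell matrix")
  .check(!is.null(gene_ids) && length(gene_ids) == nrow(counts),
         "gene_ids must name every row of counts")
  gene_ids <- as.character(gene_ids)
  .check(!anyDuplicated(gene_ids), "gene_ids must be unique")
  .check(length(cell_labels) == ncol(counts),
         "cell_labels must have one entry per cell")
  cell_labels <- as.character(cell_labels)
  v <- if (inherits(counts, "sparseMatrix")) counts@x else counts
  .check(all(is.finite(v)) && all(v >= 0) && all(v == floor(v)),
         "counts must be finite non-negative integers")
  rownames(counts) <- gene_ids
  small <- table(cell_labels) < 10L
  if (any(small))
    warning("cell type(s) with < 10 cells (unstable means): ",
            paste(names(which(small)), collapse = ", "), call. = FALSE)
  structure(list(gene_ids = gene_ids, counts = counts,
                 cell_labels = cell_labels),
            class = "labeled_counts")
}

#' @export
print.labeled_counts <- function(x, ...) {
  cat(sprintf("labeled_counts: %d genes x %d cells, %d cell types\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_labels))))
  invisible(x)
}

#' Library-size normalize and log-transform single-cell counts
#'
#' Each cell's counts are divided by the cell total, multiplied by
#' `scale_total`, and `log(1 + x)` transformed.  Cells with zero total
#' counts are excluded (their barcodes are recorded in the
#' `"excluded_cells"` attribute).
#'
#' @param counts A [labeled_counts()] object.
#' @param scale_total Per-cell target total (default 1e4).
#' @return A gene x cell matrix of normalized expression, with the matching
#'   cell labels in attribute `"cell_labels"`.
#' @export
normalize_cells <- function(counts, scale_total = 1e4) {
  .check(inherits(counts, "labeled_counts"), "counts must be labeled_counts")
  .check(.is_number(scale_total) && scale_total > 0,
         "scale_total must be a positive number")
  m <- counts$counts
  tot <- Matrix::colSums(m)
  .check(any(tot > 0), "all-zero count matrix cannot be normalized")
  keep <- tot > 0
  m <- m[, keep, drop = FALSE]
  norm <- log1p(m %*% Matrix::Diagonal(x = scale_total / tot[keep]))
  colnames(norm) <- colnames(counts$counts)[keep]
  rownames(norm) <- counts$gene_ids
  attr(norm, "cell_labels") <- counts$cell_labels[keep]
  attr(norm, "excluded_cells") <- which(!keep)
  norm
}

#' Average normalized expression by cell type
#'
#' Builds the averaged feature-expression matrix for the called targets:
#' entry `(g, t)` is the arithmetic mean of gene `g`'s normalized
#' expression over all cells labeled `t`.  Targets absent from the matrix
#' are counted, not silently dropped.
#'
#' @param norm Gene x cell normalized matrix from [normalize_cells()].
#' @param labels Cell-type label per column of `norm`; defaults to the
#'   `"cell_labels"` attribute.
#' @param target_genes Character vector of target gene ids to profile;
#'   `NULL` profiles every gene.
#' @return A `celltype_profile` (stage `"averaged"`) with fields `values`
#'   (target x type matrix), `n_unmapped` and `unmapped_genes`.
#' @export
average_by_celltype <- function(norm, labels = attr(norm, "cell_labels"),
                                target_genes = NULL) {
  .check(length(dim(norm)) == 2L, "norm must be a gene x cell matrix")
  .check(!is.null(labels) && length(labels) == ncol(norm),
         "labels must have one entry per cell")
  labels <- as.character(labels)
  if (is.null(target_genes)) target_genes <- rownames(norm)
  target_genes <- unique(as.character(target_genes))
  hit <- target_genes %in% rownames(norm)
  .check(any(hit),
         "no target gene found in the expression matrix; check id mapping")
  genes <- target_genes[hit]
  types <- sort(unique(labels))
  # gene x type sums via a sparse indicator, then divide by cells per type
  ind <- Matrix::sparseMatrix(i = seq_along(labels),
                              j = match(labels, types),
                              x = 1, dims = c(length(labels), length(types)))
  sums <- as.matrix(norm[genes, , drop = FALSE] %*% ind)
  avg <- sweep(sums, 2, as.numeric(Matrix::colSums(ind)), `/`)
  dimnames(avg) <- list(genes, types)
  structure(list(values = avg, target_genes = genes, cell_types = types,
                 stage = "averaged",
                 n_unmapped = sum(!hit),
                 unmapped_genes = target_genes[!hit]),
            class = "celltype_profile")
}

#' Row-scale an averaged profile across cell types
#'
#' Z-scores each target's row across cell types (sample SD, `ddof = 1`),
#' the standard scaling for cross-cell-type heatmaps.  Zero-variance rows
#' are set to all zeros and flagged.
#'
#' @param profile A `celltype_profile` at stage `"averaged"`.
#' @return The profile at stage `"scaled"`, with logical field
#'   `zero_variance` per row.
#' @export
scale_rows <- function(profile) {
  .check(inherits(profile, "celltype_profile"), "profile must be a celltype_profile")
  .check(identical(profile$stage, "averaged"),
         "profile must be at stage 'averaged'")
  v <- profile$values
  .check(ncol(v) >= 2L, "row scaling needs at least 2 cell types")
  mu <- rowMeans(v)
  sd <- apply(v, 1, stats::sd)
  zv <- sd <= 0 | !is.finite(sd)
  sd[zv] <- 1
  z <- (v - mu) / sd
  z[zv, ] <- 0
  profile$values <- z
  profile$stage <- "scaled"
  profile$zero_variance <- stats::setNames(zv, rownames(v))
  profile
}

#' Assign each target to the cell type with its highest scaled expression
#'
#' A target is designated cell-type-associated when one cell type holds
#' its strict row maximum; exact ties (within `tol`) and zero-variance
#' rows are reported as `"AMBIGUOUS"` and contribute to no type's count.
#'
#' @param profile A `celltype_profile` at stage `"scaled"`.
#' @param tol Tie tolerance on the scaled values (default 1e-12).
#' @return An `assignment_result` with fields `assignments` (named
#'   character, gene -> type or `"AMBIGUOUS"`), `counts` (named integer per
#'   cell type, zeros kept), `n_ambiguous`, `n_unmapped`.
#' @export
assign_targets <- function(profile, tol = 1e-12) {
  .check(inherits(profile, "celltype_profile"), "profile must be a celltype_profile")
  .check(identical(profile$stage, "scaled"), "profile must be at stage 'scaled'")
  v <- profile$values
  types <- colnames(v)
  assigned <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    row <- v[i, ]
    mx <- max(row)
    top <- which(row >= mx - tol)
    assigned[i] <- if (length(top) == 1L) types[top] else AMBIGUOUS
  }
  if (!is.null(profile$zero_variance))
    assigned[profile$zero_variance[rownames(v)]] <- AMBIGUOUS
  names(assigned) <- rownames(v)
  counts <- stats::setNames(integer(length(types)), types)
  tab <- table(assigned[assigned != AMBIGUOUS])
  counts[names(tab)] <- as.integer(tab)
  structure(list(assignments = assigned, counts = counts,
                 n_ambiguous = sum(assigned == AMBIGUOUS),
                 n_unmapped = profile$n_unmapped %||% 0L),
            class = "assignment_result")
}

#' Rank cell types by number of assigned targets
#'
#' @param result An `assignment_result` from [assign_targets()].
#' @return A data.frame (`cell_type`, `n_targets`) sorted by count
#'   descending, ties broken by cell-type name.
#' @export
rank_celltypes <- function(result) {
  .check(inherits(result, "assignment_result"),
         "result must be an assignment_result")
  df <- data.frame(cell_type = names(result$counts),
                   n_targets = as.integer(result$counts),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$n_targets, df$cell_type), , drop = FALSE]
  rownames(df) <- NULL
  df
}
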