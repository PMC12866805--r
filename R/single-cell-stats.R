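# Wilcoxon differential expression between cell groups and per-cell
# gene-set (injury) scoring on the normalized matrix.

#' Call differentially expressed genes between two cell groups
#'
#' Per gene: `log2fc = log2((mean_a + pseudocount) / (mean_b + pseudocount))`
#' on normalized expression, a two-sided Wilcoxon rank-sum p-value, BH
#' adjustment across all tested genes, and the conventional single-cell
#' gate `|log2FC| >= lfc_thresh` and adjusted p `< padj_thresh`.
#'
#' @param norm Gene x cell normalized matrix (see [normalize_cells()]).
#' @param labels Group label per column of `norm`; defaults to the
#'   `"cell_labels"` attribute.
#' @param group_a,group_b Labels of the two groups to compare
#'   (fold change is a over b).
#' @param lfc_thresh Absolute log2 fold-change threshold (default 0.25).
#' @param padj_thresh Adjusted-p threshold (default 0.05).
#' @param pseudocount Added to both group means before the ratio
#'   (default 1).
#' @return A data.frame (`gene`, `log2fc`, `p_value`, `p_adj`, `is_deg`)
#'   in the gene order of `norm`.
#' @export
call_degs <- function(norm, labels = attr(norm, "cell_labels"),
                      group_a, group_b,
                      lfc_thresh = 0.25, padj_thresh = 0.05,
                      pseudocount = 1) {
  .check(length(dim(norm)) == 2L, "norm must be a gene x cell matrix")
  .check(!is.null(labels) && length(labels) == ncol(norm),
         "labels must have one entry per cell")
  labels <- as.character(labels)
  ia <- which(labels == group_a)
  ib <- which(labels == group_b)
  .check(length(ia) > 0L, "group_a has no cells: ", group_a)
  .check(length(ib) > 0L, "group_b has no cells: ", group_b)
  m <- as.matrix(norm[, c(ia, ib), drop = FALSE])
  na <- length(ia)
  mean_a <- rowMeans(m[, seq_len(na), drop = FALSE])
  mean_b <- rowMeans(m[, -seq_len(na), drop = FALSE])
  log2fc <- log2((mean_a + pseudocount) / (mean_b + pseudocount))
  p <- vapply(seq_len(nrow(m)), function(i) {
    wilcoxon_rank_sum(m[i, seq_len(na)], m[i, -seq_len(na)])$p_value
  }, numeric(1))
  p_adj <- benjamini_hochberg(p)
  data.frame(gene = rownames(norm) %||% as.character(seq_len(nrow(norm))),
             log2fc = log2fc, p_value = p, p_adj = p_adj,
             is_deg = abs(log2fc) >= lfc_thresh & p_adj < padj_thresh,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Score cells for a gene program
#'
#' Per-cell summary of a gene set (e.g. an injury signature): each set
#' gene is z-scored across all cells (sample SD), and a cell's score is
#' the mean z over the set genes present in the matrix.  Zero-variance
#' genes contribute 0.
#'
#' @param norm Gene x cell normalized matrix.
#' @param gene_set Character vector of gene ids.
#' @param labels Optional group label per cell, carried into the output.
#' @return A data.frame (`cell`, `group`, `score`), one row per cell.
#' @export
score_gene_set <- function(norm, gene_set,
                           labels = attr(norm, "cell_labels")) {
  .check(length(dim(norm)) == 2L, "norm must be a gene x cell matrix")
  genes <- intersect(as.character(gene_set), rownames(norm))
  .check(length(genes) > 0L,
         "no gene of the set is present in the expression matrix")
  m <- as.matrix(norm[genes, , drop = FALSE])
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  zv <- sd <= 0 | !is.finite(sd)
  sd[zv] <- 1
  z <- (m - mu) / sd
  z[zv, ] <- 0
  data.frame(cell = colnames(norm) %||% as.character(seq_len(ncol(norm))),
             group = if (is.null(labels)) NA_character_ else as.character(labels),
             score = colMeans(z),
             stringsAsFactors = FALSE, row.names = NULL)
}
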