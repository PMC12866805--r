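# Competitive chemoproteomics: probe (drug-probe pull-down) channels versus
# competition (excess free drug pre-incubation) channels on one TMT plex.
# Genuine targets lose probe signal under competition, so target calling is
# a per-protein two-sample comparison of the two channel groups.

#' Construct a TMT reporter-intensity table
#'
#' @param intensities Numeric matrix, proteins x channels, strictly positive
#'   reporter intensities.  Row names are taken as protein ids if
#'   `protein_ids` is missing.
#' @param channel_groups Named character vector mapping every channel
#'   (column) to `"probe"` or `"competition"`.
#' @param protein_ids Optional character vector of unique protein ids.
#' @return A `quant_table` object.
#' @export
quant_table <- function(intensities, channel_groups, protein_ids = rownames(intensities)) {
  .check(is.matrix(intensities) && is.numeric(intensities),
         "intensities must be a numeric matrix")
  .check(!is.null(protein_ids) && length(protein_ids) == nrow(intensities),
         "protein_ids must name every row of intensities")
  protein_ids <- as.character(protein_ids)
  .check(!anyDuplicated(protein_ids), "protein_ids must be unique")
  bad <- which(!is.finite(intensities) | intensities <= 0)
  if (length(bad)) {
    cells <- arrayInd(bad, dim(intensities))
    stop("non-positive or non-finite intensities at (protein, channel): ",
         paste(sprintf("(%s, %s)", protein_ids[cells[, 1]],
                       colnames(intensities)[cells[, 2]] %||% cells[, 2]),
               collapse = ", "), call. = FALSE)
  }
  .check(!is.null(colnames(intensities)), "intensities must have channel names")
  .check(!is.null(names(channel_groups)) &&
           setequal(names(channel_groups), colnames(intensities)),
         "channel_groups must be named by the channels of intensities")
  channel_groups <- channel_groups[colnames(intensities)]
  .check(all(channel_groups %in% c("probe", "competition")),
         "channel groups must be 'probe' or 'competition'")
  .check(sum(channel_groups == "probe") >= 2L &&
           sum(channel_groups == "competition") >= 2L,
         "need >= 2 channels per group for a two-sample test")
  rownames(intensities) <- protein_ids
  structure(
    list(protein_ids = protein_ids, intensities = intensities,
         channel_groups = channel_groups),
    class = "quant_table"
  )
}

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf("quant_table: %d proteins x %d channels (%d probe, %d competition)\n",
              nrow(x$intensities), ncol(x$intensities),
              sum(x$channel_groups == "probe"),
              sum(x$channel_groups == "competition")))
  invisible(x)
}

#' Median-normalize TMT channels
#'
#' Rescales every channel so that all channel medians equal the grand
#' median of the input table, removing channel loading differences.
#' Idempotent, and invariant to a global rescaling of any channel.
#'
#' @param table A [quant_table()].
#' @return A `quant_table` with equalized channel medians.
#' @export
median_normalize <- function(table) {
  .check(inherits(table, "quant_table"), "table must be a quant_table")
  m <- table$intensities
  med <- apply(m, 2, stats::median)
  grand <- stats::median(m)
  m <- sweep(m, 2, grand / med, `*`)
  quant_table(m, table$channel_groups, table$protein_ids)
}

#' Target-calling gate parameters
#'
#' Defaults reproduce the conventional competition gate: absolute fold
#' change above 1.2 and raw p below 0.05.
#'
#' @param fc_thresh Fold-change threshold, > 1.
#' @param p_thresh P-value threshold in (0, 1).
#' @param use_adjusted_p Gate on BH-adjusted p instead of raw p.
#' @param two_sided_fc If `TRUE` (default) the gate uses `|log2FC|`;
#'   otherwise only probe-enriched proteins can pass.
#' @param welch Use Welch's unequal-variance t-test instead of the pooled
#'   Student's test.
#' @return A `gate_params` list.
#' @export
gate_params <- function(fc_thresh = 1.2, p_thresh = 0.05,
                        use_adjusted_p = FALSE, two_sided_fc = TRUE,
                        welch = FALSE) {
  .check(.is_number(fc_thresh) && fc_thresh > 1, "fc_thresh must be > 1")
  .check(.is_number(p_thresh) && p_thresh > 0 && p_thresh < 1,
         "p_thresh must be in (0, 1)")
  structure(list(fc_thresh = fc_thresh, p_thresh = p_thresh,
                 use_adjusted_p = isTRUE(use_adjusted_p),
                 two_sided_fc = isTRUE(two_sided_fc),
                 welch = isTRUE(welch)),
            class = "gate_params")
}

# Vectorised per-row two-sample t-test on a matrix (rows = proteins).
# Returns two-tailed p-values; pooled (Student) by default, Welch optional.
.row_t_test <- function(m, ia, ib, welch = FALSE) {
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(m[, ia, drop = FALSE])
  mb <- rowMeans(m[, ib, drop = FALSE])
  va <- rowSums((m[, ia, drop = FALSE] - ma)^2) / (na - 1)
  vb <- rowSums((m[, ib, drop = FALSE] - mb)^2) / (nb - 1)
  d <- ma - mb
  if (welch) {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- rep(na + nb - 2, nrow(m))
  }
  t_stat <- d / sqrt(se2)
  p <- 2 * stats::pt(-abs(t_stat), df = df)
  # degenerate zero-variance rows: equal means -> p = 1, unequal -> p = 0
  deg <- se2 <= 0
  p[deg & d == 0] <- 1
  t_stat[deg & d == 0] <- 0
  p[deg & d != 0] <- 0
  list(t_stat = t_stat, p_value = p)
}

#' Call drug-bound targets from a probe-vs-competition table
#'
#' Per protein, computes `log2fc = log2(mean(probe) / mean(competition))`
#' on (median-normalized) linear intensities, a two-tailed Student's t-test
#' on log2 intensities, BH adjustment across all proteins, and flags
#' targets passing the gate.  The output is volcano-plot ready.
#'
#' @param table A [quant_table()], normally after [median_normalize()].
#' @param gate A [gate_params()] object.
#' @return A data.frame with columns `protein_id`, `log2fc`, `p_value`,
#'   `p_adj`, `is_target`, `probe_enriched`, sorted by p-value (ties broken
#'   by protein id).
#' @export
call_targets <- function(table, gate = gate_params()) {
  .check(inherits(table, "quant_table"), "table must be a quant_table")
  .check(inherits(gate, "gate_params"), "gate must be gate_params()")
  m <- table$intensities
  ia <- which(table$channel_groups == "probe")
  ib <- which(table$channel_groups == "competition")
  log2fc <- log2(rowMeans(m[, ia, drop = FALSE]) /
                   rowMeans(m[, ib, drop = FALSE]))
  tt <- .row_t_test(log2(m), ia, ib, welch = gate$welch)
  p_adj <- benjamini_hochberg(tt$p_value)
  p_gate <- if (gate$use_adjusted_p) p_adj else tt$p_value
  fc_pass <- if (gate$two_sided_fc) abs(log2fc) > log2(gate$fc_thresh)
             else log2fc > log2(gate$fc_thresh)
  out <- data.frame(
    protein_id = table$protein_ids,
    log2fc = log2fc,
    p_value = tt$p_value,
    p_adj = p_adj,
    is_target = fc_pass & p_gate < gate$p_thresh,
    probe_enriched = log2fc > 0,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p_value, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
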