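# Synthetic-data generators with planted ground truth.  Every downstream
# stage is tested by parameter recovery against the truth these emit:
# log-normally noisy TMT intensities with a planted probe-vs-competition
# effect on true targets, negative-binomial scRNA counts with planted
# per-cell-type enrichment, and gene-set collections with one planted
# enriched term.

#' Configuration for the chemoproteomics simulator
#'
#' Emulates one competitive TMT plex: probe channels see full probe
#' engagement, competition channels have true targets blocked, so true
#' targets carry a planted probe-over-competition log2 fold change.
#'
#' @param n_proteins Number of quantified proteins.
#' @param n_true_targets Number of planted true targets
#'   (`<= n_proteins`).
#' @param planted_log2fc Planted log2(probe/competition) effect on true
#'   targets.
#' @param intensity_cv Multiplicative noise coefficient of variation of
#'   the reporter intensities (log-normal).
#' @param n_probe_channels,n_comp_channels Channels per group (each >= 2).
#' @param baseline_log10_intensity_range Range of per-protein baseline
#'   intensities, log10 scale.
#' @param seed Integer seed; identical seed gives a bit-identical table.
#' @return A `chemo_sim_config` list.
#' @export
chemo_sim_config <- function(n_proteins = 1000, n_true_targets = 50,
                             planted_log2fc = 2, intensity_cv = 0.2,
                             n_probe_channels = 3, n_comp_channels = 3,
                             baseline_log10_intensity_range = c(4.5, 7.5),
                             seed = 1) {
  .check(.is_count(n_proteins, 1), "n_proteins must be a positive count")
  .check(.is_count(n_true_targets) && n_true_targets <= n_proteins,
         "n_true_targets must be a count <= n_proteins")
  .check(.is_number(planted_log2fc), "planted_log2fc must be a finite number")
  .check(.is_number(intensity_cv) && intensity_cv > 0,
         "intensity_cv must be > 0")
  .check(.is_count(n_probe_channels, 2), "n_probe_channels must be >= 2")
  .check(.is_count(n_comp_channels, 2), "n_comp_channels must be >= 2")
  .check(is.numeric(baseline_log10_intensity_range) &&
           length(baseline_log10_intensity_range) == 2L &&
           diff(baseline_log10_intensity_range) >= 0,
         "baseline_log10_intensity_range must be an increasing pair")
  .check(.is_count(abs(seed)), "seed must be an integer")
  structure(as.list(environment()), class = "chemo_sim_config")
}

#' Simulate a competitive chemoproteomics TMT table
#'
#' Per protein, a baseline intensity is drawn log-uniformly from the
#' configured log10 range; every channel value is baseline times
#' multiplicative log-normal noise with the configured CV (sdlog from the
#' log-normal identity `sdlog^2 = log(1 + cv^2)`, mean-one noise); probe
#' channels of planted targets are additionally multiplied by
#' `2^planted_log2fc`.
#'
#' @param cfg A [chemo_sim_config()].
#' @return A list with `quant` (a [quant_table()]) and `truth` (fields
#'   `true_target_ids`).
#' @export
simulate_chemoproteomics <- function(cfg = chemo_sim_config()) {
  .check(inherits(cfg, "chemo_sim_config"), "cfg must be a chemo_sim_config")
  with_seed(cfg$seed, {
    np <- cfg$n_proteins
    ids <- sprintf("P%05d", seq_len(np))
    channels <- c(sprintf("probe_%d", seq_len(cfg$n_probe_channels)),
                  sprintf("comp_%d", seq_len(cfg$n_comp_channels)))
    groups <- stats::setNames(
      rep(c("probe", "competition"),
          c(cfg$n_probe_channels, cfg$n_comp_channels)), channels)
    baseline <- 10^stats::runif(np, cfg$baseline_log10_intensity_range[1],
                                cfg$baseline_log10_intensity_range[2])
    sdlog <- sqrt(log(1 + cfg$intensity_cv^2))
    nc <- length(channels)
    noise <- matrix(stats::rlnorm(np * nc, meanlog = -sdlog^2 / 2,
                                  sdlog = sdlog), np, nc)
    m <- baseline * noise
    targets <- sort(sample.int(np, cfg$n_true_targets))
    m[targets, seq_len(cfg$n_probe_channels)] <-
      m[targets, seq_len(cfg$n_probe_channels)] * 2^cfg$planted_log2fc
    colnames(m) <- channels
    rownames(m) <- ids
    list(quant = quant_table(m, groups, ids),
         truth = list(true_target_ids = ids[targets]))
  })
}

#' Configuration for the scRNA-seq count simulator
#'
#' Negative-binomial counts parameterized by (mean, dispersion) with
#' `variance = mean + mean^2 / dispersion`, the conventional scRNA-seq
#' count model.  Planted target genes have their mean multiplied by
#' `fold` in cells of their home type.
#'
#' @param cell_types Ordered character vector of cell-type names.
#' @param cells_per_type Cells simulated per type.
#' @param n_genes Number of genes.
#' @param baseline_mean NB mean per gene per cell.
#' @param dispersion NB size parameter (> 0).
#' @param planted_genes `NULL`, or a data.frame with columns `gene`
#'   (id in `gene0001` style or integer index), `home_type`, `fold`
#'   (>= 1).
#' @param seed Integer seed.
#' @return An `sc_sim_config` list.
#' @export
sc_sim_config <- function(cell_types = c("PT", "LOH", "DT", "CD", "EC",
                                         "Podocyte", "Macrophage", "Tcell"),
                          cells_per_type = 200, n_genes = 2000,
                          baseline_mean = 1, dispersion = 2,
                          planted_genes = NULL, seed = 1) {
  .check(is.character(cell_types) && length(cell_types) >= 1L &&
           !anyDuplicated(cell_types), "cell_types must be unique names")
  .check(.is_count(cells_per_type, 1), "cells_per_type must be >= 1")
  .check(.is_count(n_genes, 1), "n_genes must be >= 1")
  .check(.is_number(baseline_mean) && baseline_mean > 0,
         "baseline_mean must be > 0")
  .check(.is_number(dispersion) && dispersion > 0, "dispersion must be > 0")
  if (!is.null(planted_genes)) {
    .check(is.data.frame(planted_genes) &&
             all(c("gene", "home_type", "fold") %in% names(planted_genes)),
           "planted_genes needs columns gene, home_type, fold")
    .check(all(planted_genes$home_type %in% cell_types),
           "every home_type must appear in cell_types")
    .check(all(planted_genes$fold >= 1), "enrichment fold must be >= 1")
    if (is.numeric(planted_genes$gene)) {
      .check(all(planted_genes$gene >= 1 & planted_genes$gene <= n_genes),
             "planted gene index out of range")
      planted_genes$gene <- sprintf("gene%04d", planted_genes$gene)
    }
  }
  .check(.is_count(abs(seed)), "seed must be an integer")
  structure(as.list(environment()), class = "sc_sim_config")
}

#' Simulate a cell-type-labeled scRNA-seq count matrix
#'
#' @param cfg An [sc_sim_config()].
#' @return A list with `counts` (a [labeled_counts()], sparse) and `truth`
#'   (field `target_home_celltype`, a named character vector gene -> home
#'   type).
#' @export
simulate_scrna <- function(cfg = sc_sim_config()) {
  .check(inherits(cfg, "sc_sim_config"), "cfg must be an sc_sim_config")
  with_seed(cfg$seed, {
    genes <- sprintf("gene%04d", seq_len(cfg$n_genes))
    labels <- rep(cfg$cell_types, each = cfg$cells_per_type)
    ncell <- length(labels)
    mu <- matrix(cfg$baseline_mean, cfg$n_genes, ncell)
    truth_map <- stats::setNames(character(0), character(0))
    if (!is.null(cfg$planted_genes)) {
      pg <- cfg$planted_genes
      .check(all(pg$gene %in% genes), "planted gene index out of range")
      for (i in seq_len(nrow(pg))) {
        gi <- match(pg$gene[i], genes)
        mu[gi, labels == pg$home_type[i]] <-
          cfg$baseline_mean * pg$fold[i]
      }
      truth_map <- stats::setNames(as.character(pg$home_type), pg$gene)
    }
    counts <- matrix(stats::rnbinom(length(mu), size = cfg$dispersion,
                                    mu = mu),
                     cfg$n_genes, ncell,
                     dimnames = list(genes,
                                     sprintf("cell%05d", seq_len(ncell))))
    list(counts = labeled_counts(Matrix::Matrix(counts, sparse = TRUE),
                                 labels, genes),
         truth = list(target_home_celltype = truth_map))
  })
}

#' Simulate a gene-set collection with one planted enriched term
#'
#' All sets are sampled uniformly from the universe, except one planted
#' set constructed to overlap a designated query by exactly
#' `planted_overlap` genes.
#'
#' @param n_sets Number of sets.
#' @param set_size_range Integer pair, inclusive range of set sizes.
#' @param universe Character vector of background gene ids.
#' @param query Character vector, the designated query (subset of the
#'   universe).
#' @param planted_overlap Overlap between the planted set and the query
#'   (`<= min(length(query), max(set_size_range))`).
#' @param seed Integer seed.
#' @return A list with `collection` (a [gene_set_collection()]) and
#'   `truth` (field `enriched_term_id`).
#' @export
simulate_gene_sets <- function(n_sets = 50, set_size_range = c(10, 50),
                               universe, query, planted_overlap, seed = 1) {
  .check(.is_count(n_sets, 1), "n_sets must be >= 1")
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  .check(all(query %in% universe), "query must be a subset of the universe")
  .check(is.numeric(set_size_range) && length(set_size_range) == 2L &&
           set_size_range[1] >= 1 &&
           set_size_range[2] <= length(universe) &&
           diff(set_size_range) >= 0,
         "set_size_range must be an increasing pair within the universe size")
  .check(.is_count(planted_overlap), "planted_overlap must be a count")
  .check(planted_overlap <= set_size_range[2],
         "planted overlap larger than the maximum set size")
  .check(planted_overlap <= length(query),
         "planted overlap larger than the query")
  with_seed(seed, {
    sizes <- sample(set_size_range[1]:set_size_range[2], n_sets,
                    replace = TRUE)
    planted_idx <- sample.int(n_sets, 1)
    sizes[planted_idx] <- max(sizes[planted_idx], planted_overlap)
    ids <- sprintf("SET%03d", seq_len(n_sets))
    non_query <- setdiff(universe, query)
    sets <- lapply(seq_len(n_sets), function(i) {
      genes <- if (i == planted_idx) {
        extra <- sizes[i] - planted_overlap
        .check(extra <= length(non_query),
               "planted set size exceeds available non-query genes")
        c(sample(query, planted_overlap), sample(non_query, extra))
      } else {
        sample(universe, sizes[i])
      }
      list(description = if (i == planted_idx) "planted term" else "random term",
           genes = genes)
    })
    names(sets) <- ids
    list(collection = gene_set_collection(sets, universe),
         truth = list(enriched_term_id = ids[planted_idx]))
  })
}
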