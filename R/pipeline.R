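# One reproducible run: simulate (or load) -> call targets -> integrate
# onto cell types -> assign -> differential expression -> enrichment, with
# a machine-readable report.  All randomness is funneled through one seed;
# per-stage sub-seeds are derived deterministically so reruns with the same
# config are bit-identical on simulated inputs.

#' Default demo run configuration
#'
#' A fully simulated end-to-end run: a competitive TMT plex with planted
#' targets, a kidney-like labeled count matrix in which the true targets'
#' genes are planted into one home cell type, and a gene-set collection
#' with one planted term overlapping the called targets.
#'
#' @param seed Integer master seed.
#' @param outdir Output directory.
#' @return A nested list, YAML-serializable, accepted by [run_pipeline()].
#' @export
demo_run_config <- function(seed = 1, outdir = tempfile("step_run_")) {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    chemoproteomics = list(simulate = list(
      n_proteins = 400, n_true_targets = 50, planted_log2fc = 2,
      intensity_cv = 0.1, n_probe_channels = 3, n_comp_channels = 3)),
    gate = list(fc_thresh = 1.2, p_thresh = 0.05),
    scrna = list(simulate = list(
      cell_types = c("PT", "LOH", "DT", "CD", "EC",
                     "Podocyte", "Macrophage", "Tcell"),
      cells_per_type = 150, n_genes = 400,
      baseline_mean = 1, dispersion = 2,
      plant = list(home_type = "PT", fold = 4))),
    normalize = list(scale_total = 10000),
    deg = list(group_a = "PT", group_b = "EC",
               lfc_thresh = 0.25, padj_thresh = 0.05),
    enrichment = list(simulate = list(
      n_sets = 40, set_size_range = c(10, 50), planted_overlap_frac = 0.8),
      min_set = 5, max_set = 500)
  )
}

# protein id -> gene id map used for simulated runs: protein P000k pairs
# with gene000k, so chemoproteomics truth and scRNA planting stay coherent.
.sim_protein_gene_map <- function(protein_ids, n_genes) {
  idx <- as.integer(sub("^P0*", "", protein_ids))
  ok <- idx >= 1 & idx <= n_genes
  data.frame(protein_id = protein_ids[ok],
             gene = sprintf("gene%04d", idx[ok]),
             stringsAsFactors = FALSE)
}

#' Run the full target-profiling pipeline
#'
#' Executes all stages in order, writes every stage output under
#' `config$outdir`, and returns (and writes) a run report whose counts
#' satisfy the conservation identity
#' `assigned + ambiguous + unmapped = called targets`.
#'
#' @param config A nested list as produced by [demo_run_config()] or read
#'   from YAML (see `step_profiler_cli()`); each omics stage holds either a
#'   `simulate` block or an `input` block with file paths.
#' @return The run report, invisibly (also written as `report.json`).
#' @export
run_pipeline <- function(config) {
  .check(is.list(config) && .is_count(abs(config$seed %||% -1)),
         "config must be a list with an integer seed")
  .check(!is.null(config$outdir), "config must name an outdir")
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  stages <- character(0)
  stage <- function(name, expr) {
    stages <<- c(stages, name)
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  ## chemoproteomics: quantify and call targets
  quant <- stage("chemoproteomics", {
    cc <- config$chemoproteomics
    if (!is.null(cc$simulate)) {
      args <- cc$simulate
      args$seed <- derive_seed(seed, 1L)
      sim <- simulate_chemoproteomics(do.call(chemo_sim_config, args))
      jsonlite::write_json(sim$truth, file.path(outdir, "chemo_truth.json"),
                           auto_unbox = TRUE)
      sim$quant
    } else {
      read_quant_tsv(cc$input$quant, cc$input$groups)
    }
  })
  calls <- stage("call_targets", {
    g <- do.call(gate_params, config$gate %||% list())
    normq <- median_normalize(quant)
    write_quant_tsv(normq, file.path(outdir, "quant_normalized.tsv"))
    calls <- call_targets(normq, g)
    write_tsv(calls, file.path(outdir, "target_calls.tsv"))
    calls
  })
  called <- calls$protein_id[calls$is_target]

  ## scRNA-seq: counts, labels, normalization
  sc <- stage("scrna", {
    scc <- config$scrna
    if (!is.null(scc$simulate)) {
      args <- scc$simulate
      plant <- args$plant
      args$plant <- NULL
      args$seed <- derive_seed(seed, 2L)
      args$cell_types <- as.character(unlist(args$cell_types))
      if (!is.null(plant)) {
        # plant the TRUE chemoproteomics targets' genes (ground truth, not
        # the calls) into the configured home type
        truth <- jsonlite::read_json(file.path(outdir, "chemo_truth.json"),
                                     simplifyVector = TRUE)
        map <- .sim_protein_gene_map(truth$true_target_ids, args$n_genes)
        args$planted_genes <- data.frame(
          gene = map$gene, home_type = plant$home_type, fold = plant$fold,
          stringsAsFactors = FALSE)
      }
      sim <- simulate_scrna(do.call(sc_sim_config, args))
      write_counts_mtx(sim$counts, file.path(outdir, "counts"))
      jsonlite::write_json(as.list(sim$truth$target_home_celltype),
                           file.path(outdir, "scrna_truth.json"),
                           auto_unbox = TRUE)
      sim$counts
    } else {
      read_counts_mtx(scc$input$dir)
    }
  })
  norm <- stage("normalize", {
    normalize_cells(sc, scale_total = config$normalize$scale_total %||% 1e4)
  })

  ## integrate: map called proteins to genes, average, scale, assign
  map <- stage("id_map", {
    if (!is.null(config$map)) {
      utils::read.delim(config$map, stringsAsFactors = FALSE)
    } else {
      .sim_protein_gene_map(quant$protein_ids, nrow(sc$counts))
    }
  })
  target_genes <- unique(map$gene[match(called, map$protein_id, nomatch = 0)])
  result <- stage("integrate", {
    prof <- average_by_celltype(norm, target_genes = c(
      target_genes, setdiff(called, map$protein_id)))
    write_tsv(data.frame(gene = rownames(prof$values), prof$values,
                         check.names = FALSE),
              file.path(outdir, "profile_averaged.tsv"))
    scaled <- scale_rows(prof)
    write_tsv(data.frame(gene = rownames(scaled$values), scaled$values,
                         check.names = FALSE),
              file.path(outdir, "profile_scaled.tsv"))
    res <- assign_targets(scaled)
    write_tsv(data.frame(gene = names(res$assignments),
                         cell_type = unname(res$assignments)),
              file.path(outdir, "assignments.tsv"))
    jsonlite::write_json(as.list(res$counts),
                         file.path(outdir, "celltype_counts.json"),
                         auto_unbox = TRUE)
    res
  })
  ranking <- rank_celltypes(result)

  ## differential expression between two configured groups
  degs <- stage("deg", {
    dc <- config$deg
    if (is.null(dc)) NULL else {
      d <- call_degs(norm, group_a = dc$group_a, group_b = dc$group_b,
                     lfc_thresh = dc$lfc_thresh %||% 0.25,
                     padj_thresh = dc$padj_thresh %||% 0.05)
      write_tsv(d, file.path(outdir, "degs.tsv"))
      d
    }
  })

  ## enrichment of the mapped called targets
  enr <- stage("enrich", {
    ec <- config$enrichment
    if (is.null(ec)) NULL else {
      query <- target_genes
      coll <- if (!is.null(ec$simulate)) {
        es <- ec$simulate
        ssr <- as.integer(unlist(es$set_size_range %||% c(10, 50)))
        overlap <- min(length(query),
                       floor((es$planted_overlap_frac %||% 0.8) *
                               min(length(query), ssr[2])))
        sim <- simulate_gene_sets(
          n_sets = es$n_sets %||% 40, set_size_range = ssr,
          universe = rownames(norm), query = query,
          planted_overlap = overlap, seed = derive_seed(seed, 3L))
        write_gmt(sim$collection, file.path(outdir, "gene_sets.gmt"))
        jsonlite::write_json(sim$truth,
                             file.path(outdir, "genesets_truth.json"),
                             auto_unbox = TRUE)
        sim$collection
      } else {
        read_gmt(ec$input$gmt, universe = rownames(norm))
      }
      e <- enrich(query, coll, min_set = ec$min_set %||% 5,
                  max_set = ec$max_set %||% 500)
      write_tsv(e, file.path(outdir, "enrichment.tsv"))
      e
    }
  })

  n_called <- length(called)
  n_assigned <- sum(result$counts)
  report <- list(
    software = list(package = "stepprofiler",
                    version = as.character(utils::packageVersion("stepprofiler"))),
    seed = seed,
    stages = stages,
    counts = list(
      proteins_quantified = nrow(quant$intensities),
      targets_called = n_called,
      targets_mapped = length(target_genes),
      targets_assigned = n_assigned,
      targets_ambiguous = result$n_ambiguous,
      targets_unmapped = n_called - n_assigned - result$n_ambiguous,
      degs = if (is.null(degs)) NA else sum(degs$is_deg),
      enriched_terms = if (is.null(enr)) NA else sum(enr$p_adj < 0.05)
    ),
    top_cell_type = ranking$cell_type[1],
    celltype_ranking = ranking,
    parameters = config[setdiff(names(config), "outdir")]
  )
  stopifnot(report$counts$targets_assigned + report$counts$targets_ambiguous +
              report$counts$targets_unmapped == report$counts$targets_called)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
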