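test_that("normalize_cells applies library-size log-normalization per cell", {
  m <- matrix(c(2, 8), 2, 1)
  lc <- make_counts(m, "A")
  norm <- normalize_cells(lc, scale_total = 1e4)
  expect_equal(as.numeric(norm), c(log1p(2000), log1p(8000)),
               tolerance = 1e-12)

  # all-zero gene stays zero; zero-total cell is excluded and flagged
  m2 <- cbind(c(2, 8, 0), c(0, 0, 0), c(4, 4, 0))
  lc2 <- make_counts(m2, c("A", "A", "B"))
  norm2 <- normalize_cells(lc2)
  expect_equal(ncol(norm2), 2L)
  expect_equal(unname(attr(norm2, "excluded_cells")), 2L)
  expect_identical(attr(norm2, "cell_labels"), c("A", "B"))
  expect_equal(as.numeric(norm2[3, ]), c(0, 0))

  # duplicating every cell leaves per-cell values unchanged
  lc3 <- make_counts(cbind(m2[, 1], m2[, 1]), c("A", "A"))
  norm3 <- normalize_cells(lc3)
  expect_equal(as.numeric(norm3[, 1]), as.numeric(norm3[, 2]))

  expect_error(normalize_cells(make_counts(matrix(0, 2, 2), c("A", "B"))),
               "all-zero")
})

test_that("average_by_celltype matches a brute-force per-type loop", {
  set.seed(31)
  m <- matrix(rpois(3 * 4, 5), 3, 4)
  labels <- c("A", "B", "A", "B")
  norm <- normalize_cells(make_counts(m, labels))
  prof <- average_by_celltype(norm, target_genes = c("g01", "g02", "g03"))
  expect_identical(prof$stage, "averaged")
  dense <- as.matrix(norm)
  for (g in rownames(prof$values)) {
    for (t in colnames(prof$values)) {
      expect_equal(prof$values[g, t], mean(dense[g, labels == t]),
                   tolerance = 1e-12)
    }
  }
  # one cell per type: profile row equals that cell's normalized values
  norm1 <- normalize_cells(make_counts(m[, 1:2], c("A", "B")))
  prof1 <- average_by_celltype(norm1)
  expect_equal(unname(prof1$values), unname(as.matrix(norm1)),
               tolerance = 1e-12)
  # unmapped targets are counted, not dropped
  p2 <- average_by_celltype(norm, target_genes = c("g01", "nope"))
  expect_equal(p2$n_unmapped, 1L)
  expect_identical(p2$unmapped_genes, "nope")
  expect_error(average_by_celltype(norm, target_genes = "nope"),
               "id mapping")
})

test_that("scale_rows z-scores rows with sample SD and flags degeneracy", {
  v <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
  prof <- structure(list(values = v, stage = "averaged", n_unmapped = 0L),
                    class = "celltype_profile")
  s <- scale_rows(prof)
  expect_equal(unname(s$values["a", ]), c(-1, 0, 1))
  expect_equal(unname(s$values["b", ]), c(0, 0, 0))
  expect_true(s$zero_variance["b"])
  expect_false(s$zero_variance["a"])

  set.seed(32)
  big <- structure(list(values = matrix(rnorm(50 * 6), 50, 6,
                                        dimnames = list(NULL, LETTERS[1:6])),
                        stage = "averaged"), class = "celltype_profile")
  z <- scale_rows(big)$values
  expect_lt(max(abs(rowMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-9)

  one <- structure(list(values = v[, 1, drop = FALSE], stage = "averaged"),
                   class = "celltype_profile")
  expect_error(scale_rows(one), "at least 2 cell types")
  expect_error(scale_rows(s), "averaged")
})

test_that("assign_targets is a strict argmax with AMBIGUOUS ties", {
  v <- rbind(g1 = c(PT = 2, EC = 0, DT = -1),
             g2 = c(PT = 1, EC = 1, DT = 0),
             g3 = c(PT = 0, EC = 0, DT = 0))
  prof <- structure(list(values = v, stage = "scaled", n_unmapped = 2L,
                         zero_variance = c(g1 = FALSE, g2 = FALSE,
                                           g3 = TRUE)),
                    class = "celltype_profile")
  res <- assign_targets(prof)
  expect_identical(unname(res$assignments),
                   c("PT", "AMBIGUOUS", "AMBIGUOUS"))
  expect_equal(res$counts, c(PT = 1L, EC = 0L, DT = 0L))
  expect_equal(res$n_ambiguous, 2L)
  expect_equal(sum(res$counts),
               length(res$assignments) - res$n_ambiguous)  # conservation
})

test_that("assign_targets equals exhaustive row-max search on random profiles", {
  set.seed(33)
  for (rep in 1:10) {
    v <- matrix(rnorm(20 * 8), 20, 8,
                dimnames = list(sprintf("g%02d", 1:20), LETTERS[1:8]))
    # engineer ties on a few rows
    v[1, ] <- 0
    v[2, c(1, 5)] <- max(v[2, ]) + 1
    prof <- structure(list(values = v, stage = "scaled"),
                      class = "celltype_profile")
    got <- assign_targets(prof)$assignments
    want <- apply(v, 1, function(row) {
      top <- which(row >= max(row) - 1e-12)
      if (length(top) == 1) colnames(v)[top] else "AMBIGUOUS"
    })
    expect_identical(unname(got), unname(want))
  }
})

test_that("rank_celltypes sorts by count then name, and handles empties", {
  res <- structure(list(assignments = character(0),
                        counts = c(PT = 40L, Macrophage = 5L,
                                   Endothelial = 3L),
                        n_ambiguous = 0L, n_unmapped = 0L),
                   class = "assignment_result")
  r <- rank_celltypes(res)
  expect_identical(r$cell_type, c("PT", "Macrophage", "Endothelial"))

  res$counts <- c(B = 0L, A = 0L, C = 0L)
  expect_identical(rank_celltypes(res)$cell_type, c("A", "B", "C"))

  res$counts <- c(B = 2L, A = 2L, C = 5L)
  expect_identical(rank_celltypes(res)$cell_type, c("C", "A", "B"))
})

test_that("the STEP chain is invariant to cell and gene order", {
  pg <- data.frame(gene = 1:10, home_type = "B", fold = 4)
  sim <- simulate_scrna(sc_sim_config(cell_types = c("A", "B", "C"),
                                      cells_per_type = 40, n_genes = 60,
                                      planted_genes = pg, seed = 34))
  targets <- sprintf("gene%04d", 1:10)
  run <- function(lc) {
    norm <- normalize_cells(lc)
    assign_targets(scale_rows(average_by_celltype(
      norm, target_genes = targets)))$assignments
  }
  base <- run(sim$counts)
  set.seed(35)
  cp <- sample(ncol(sim$counts$counts))
  gp <- sample(nrow(sim$counts$counts))
  shuffled <- labeled_counts(sim$counts$counts[gp, cp],
                             sim$counts$cell_labels[cp],
                             sim$counts$gene_ids[gp])
  expect_identical(run(shuffled), base)
})

test_that("MTX directory round-trips labeled counts", {
  sim <- simulate_scrna(sc_sim_config(cell_types = c("A", "B"),
                                      cells_per_type = 15, n_genes = 25,
                                      seed = 36))
  d <- tempfile("mtx_")
  write_counts_mtx(sim$counts, d)
  back <- read_counts_mtx(d)
  expect_equal(as.matrix(back$counts), as.matrix(sim$counts$counts))
  expect_identical(back$cell_labels, sim$counts$cell_labels)
  expect_identical(back$gene_ids, sim$counts$gene_ids)
})
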