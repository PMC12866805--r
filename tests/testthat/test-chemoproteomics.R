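test_that("quant_table validation names offending cells and groups", {
  m <- matrix(c(1, 2, 3, 4), 2, 2,
              dimnames = list(c("A", "B"), c("probe_1", "comp_1")))
  expect_error(quant_table(m, c(probe_1 = "probe", comp_1 = "competition")),
               ">= 2 channels")
  m2 <- matrix(1, 2, 4, dimnames = list(c("A", "B"),
                                        c("p1", "p2", "c1", "c2")))
  grp <- setNames(rep(c("probe", "competition"), each = 2), colnames(m2))
  m2["B", "c1"] <- -1
  expect_error(quant_table(m2, grp), "\\(B, c1\\)")
  m2["B", "c1"] <- 1
  expect_error(quant_table(m2, grp, c("A", "A")), "unique")
  expect_s3_class(quant_table(m2, grp), "quant_table")
})

test_that("median_normalize: fixed point, scale invariance, idempotence", {
  q <- make_quant(c(10, 20, 40), c(10, 20, 40))
  eq <- median_normalize(q)
  # channel medians already equal -> output equals input
  meq <- cbind(c(10, 20, 40), c(20, 40, 10), c(40, 10, 20),
               c(10, 40, 20), c(20, 10, 40), c(40, 20, 10))
  dimnames(meq) <- list(c("A", "B", "C"),
                        c(paste0("probe_", 1:3), paste0("comp_", 1:3)))
  qeq <- quant_table(meq, setNames(rep(c("probe", "competition"), each = 3),
                                   colnames(meq)))
  expect_equal(median_normalize(qeq)$intensities, qeq$intensities)

  # multiplying one channel by 2 then normalizing equals normalizing the
  # original (the grand median is robust to one channel's rescaling here)
  q2 <- qeq
  q2$intensities[, 1] <- q2$intensities[, 1] * 2
  expect_equal(median_normalize(q2)$intensities,
               median_normalize(qeq)$intensities, tolerance = 1e-12)
  # idempotence
  expect_equal(median_normalize(eq)$intensities, eq$intensities,
               tolerance = 1e-12)
  # all channel medians equal the grand median of the input
  expect_equal(unname(apply(eq$intensities, 2, median)),
               rep(median(q$intensities), 6))
})

test_that("call_targets applies the fold-change and p gates", {
  # protein T: FC = 1.5 (log2fc ~ 0.585), tiny within-group jitter -> tiny p
  # protein F: FC = 1.1, equally small p -> fails the FC gate
  # protein N: FC = 1 -> fails both
  q <- make_quant(c(150, 110, 100), c(100, 100, 100),
                  ids = c("T", "F", "N"))
  calls <- call_targets(q)
  expect_true(calls$is_target[calls$protein_id == "T"])
  expect_lt(calls$p_value[calls$protein_id == "T"], 0.05)
  expect_equal(calls$log2fc[calls$protein_id == "T"], log2(1.5),
               tolerance = 1e-4)
  expect_false(calls$is_target[calls$protein_id == "F"])
  expect_lt(calls$p_value[calls$protein_id == "F"], 0.05)
  expect_false(calls$is_target[calls$protein_id == "N"])

  # two-sided gate: competition-enriched protein also passes
  qd <- make_quant(c(100), c(150), ids = "D")
  cd <- call_targets(qd)
  expect_true(cd$is_target)
  expect_false(cd$probe_enriched)
  expect_false(call_targets(qd, gate_params(two_sided_fc = FALSE))$is_target)
})

test_that("swapping group labels negates log2fc and preserves p", {
  sim <- simulate_chemoproteomics(chemo_sim_config(n_proteins = 100, n_true_targets = 10,
                                                   seed = 21))
  q <- sim$quant
  swapped <- q
  swapped$channel_groups <- ifelse(q$channel_groups == "probe",
                                   "competition", "probe")
  names(swapped$channel_groups) <- names(q$channel_groups)
  a <- call_targets(q); b <- call_targets(swapped)
  b <- b[match(a$protein_id, b$protein_id), ]
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
})

test_that("call_targets is invariant to input row order", {
  sim <- simulate_chemoproteomics(chemo_sim_config(n_proteins = 80, n_true_targets = 10,
                                                   seed = 22))
  q <- sim$quant
  perm <- sample(nrow(q$intensities))
  qp <- quant_table(q$intensities[perm, ], q$channel_groups,
                    q$protein_ids[perm])
  expect_equal(call_targets(q), call_targets(qp))
})

test_that("per-protein t-test on log2 intensities matches scalar oracle", {
  sim <- simulate_chemoproteomics(chemo_sim_config(n_proteins = 40, n_true_targets = 5,
                                                   seed = 23))
  calls <- call_targets(sim$quant)
  lg <- log2(sim$quant$intensities)
  for (id in sim$quant$protein_ids[1:10]) {
    ref <- student_t_test(lg[id, 1:3], lg[id, 4:6])
    expect_equal(calls$p_value[calls$protein_id == id], ref$p_value,
                 tolerance = 1e-12)
  }
  expect_equal(calls$p_adj, benjamini_hochberg(calls$p_value))
})

test_that("planted targets are recovered and false positives controlled", {
  sim <- simulate_chemoproteomics(chemo_sim_config(
    n_proteins = 1000, n_true_targets = 50, planted_log2fc = 2,
    intensity_cv = 0.1, seed = 24))
  calls <- call_targets(median_normalize(sim$quant))
  hit <- calls$protein_id[calls$is_target]
  expect_gte(mean(sim$truth$true_target_ids %in% hit), 0.95)
  fp <- mean(setdiff(calls$protein_id, sim$truth$true_target_ids) %in% hit)
  expect_lte(fp, 0.05 + 3 * sqrt(0.05 * 0.95 / 950))
})

test_that("quant TSV round-trips and drops incomplete proteins", {
  sim <- simulate_chemoproteomics(chemo_sim_config(n_proteins = 20, n_true_targets = 5,
                                                   seed = 25))
  f <- tempfile(fileext = ".tsv")
  write_quant_tsv(sim$quant, f)
  back <- read_quant_tsv(f)
  expect_equal(back$intensities, sim$quant$intensities, tolerance = 1e-6)
  expect_identical(back$channel_groups, sim$quant$channel_groups)

  # poison one cell: that protein is dropped with a message
  df <- read.delim(f, check.names = FALSE)
  df[3, 2] <- NA
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(dropped <- read_quant_tsv(f), "1 protein")
  expect_equal(nrow(dropped$intensities), 19L)
})
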