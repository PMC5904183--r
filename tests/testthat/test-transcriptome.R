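test_that("expression floor removes probes strictly below the floor mean", {
  pm <- toy_matrix(rbind(p_low = c(4.8, 5.0), p_edge = c(5.0, 5.0),
                         p_high = c(8, 9)),
                   conditions = c("stiff", "soft"))
  kept <- filter_expressed(pm, floor = 5)
  expect_setequal(rownames(kept$expr), c("p_edge", "p_high"))

  all_high <- toy_matrix(matrix(6, 4, 2), conditions = c("stiff", "soft"))
  expect_identical(filter_expressed(all_high, 5)$expr, all_high$expr)
})

test_that("floor is computed over the samples of the requested contrast", {
  # probe passes the floor in the stiff/soft contrast but not overall
  expr <- rbind(p1 = c(6, 6, 1, 1))
  colnames(expr) <- c("a1", "b1", "c1", "c2")
  pm <- probe_matrix(expr, data.frame(probe_id = "p1", gene_id = "g1"),
                     data.frame(sample_id = colnames(expr),
                                condition = c("stiff", "soft", "kd", "kd")))
  expect_equal(nrow(filter_expressed(pm, 5, c("stiff", "soft"))$expr), 1)
  expect_error(filter_expressed(pm, 5), "floor")
})

test_that("probe log2 fold change is the difference of condition means", {
  pm <- toy_matrix(rbind(p1 = c(7, 7, 8, 8), p2 = c(6, 8, 7, 7)),
                   conditions = c("stiff", "stiff", "soft", "soft"))
  fc <- probe_log2fc(pm, "stiff", "soft")
  expect_equal(fc$log2fc, c(1, 0))
  expect_equal(probe_log2fc(pm, "soft", "soft")$log2fc, c(0, 0))
  expect_error(probe_log2fc(pm, "stiff", "oss"), "design error")
})

test_that("probe fold changes match brute-force recomputation on synthetic data", {
  sim <- simulate_probe_matrix(array_sim_config(n_genes = 40, seed = 11))
  pm <- sim$matrix
  fc <- probe_log2fc(pm, "ctrl-stiff", "ctrl-soft")
  a <- pm$design$sample_id[pm$design$condition == "ctrl-stiff"]
  b <- pm$design$sample_id[pm$design$condition == "ctrl-soft"]
  manual <- vapply(seq_len(nrow(pm$expr)), function(i) {
    sa <- 0; for (s in a) sa <- sa + pm$expr[i, s]
    sb <- 0; for (s in b) sb <- sb + pm$expr[i, s]
    sb / length(b) - sa / length(a)
  }, 0)
  expect_equal(fc$log2fc, manual)
})

test_that("gene calling applies the minimum-probe rule and averages regulated probes", {
  fcs <- data.frame(
    probe_id = sprintf("p%d", 1:6),
    gene_id = c("gA", "gA", "gB", "gB", "gB", "gB"),
    log2fc = c(1.0, 1.0, 0.8, 0.6, 0.7, 0.1))
  calls <- call_genes(fcs, threshold = 0.5, min_probes = 3)
  expect_equal(calls$status[calls$gene_id == "gA"], "unregulated")
  expect_equal(calls$status[calls$gene_id == "gB"], "up")
  expect_equal(calls$avg_log2fc_regulated[calls$gene_id == "gB"], 0.7)
  expect_setequal(calls$regulated_probe_ids[calls$gene_id == "gB"][[1]],
                  c("p3", "p4", "p5"))
  expect_error(call_genes(fcs, min_probes = 0), "parameter error")
})

test_that("bidirectional genes are flagged, excluded from sets, and counted", {
  fcs <- data.frame(
    probe_id = sprintf("p%d", 1:10),
    gene_id = c(rep("gBi", 6), rep("gUp", 4)),
    log2fc = c(0.9, 0.8, 0.7, -0.6, -0.7, -0.9, 0.6, 0.7, 0.8, 0))
  calls <- call_genes(fcs, 0.5, 3)
  expect_equal(calls$status[calls$gene_id == "gBi"], "bidirectional")
  expect_true(is.na(calls$avg_log2fc_regulated[calls$gene_id == "gBi"]))
  sets <- regulated_sets(calls)
  expect_identical(sets$up, "gUp")
  expect_length(sets$down, 0)
  expect_equal(attr(calls, "bidirectional_fraction"), 0.5)
})

test_that("gene calling agrees with a brute-force oracle over a parameter grid", {
  for (seed in 1:6) {
    fcs <- random_probe_fcs(n_genes = sample(5:20, 1), seed = seed)
    for (threshold in c(0.3, 0.5, 0.8)) {
      for (min_probes in 1:3) {
        got <- call_genes(fcs, threshold, min_probes)
        want <- oracle_call_genes(fcs, threshold, min_probes)
        got <- got[order(got$gene_id), ]
        want <- want[order(want$gene_id), ]
        expect_equal(got$status, want$status,
                     info = sprintf("seed %d thr %g mp %d", seed, threshold,
                                    min_probes))
        expect_equal(got$avg_log2fc_regulated, want$avg_log2fc_regulated)
      }
    }
  }
})

test_that("regulated-gene count is monotone in threshold, min_probes and floor", {
  sim <- simulate_probe_matrix(array_sim_config(n_genes = 150, noise_sd = 0.3,
                                                seed = 21))
  n_reg <- function(floor, threshold, min_probes) {
    calls <- call_stiffness_genes(sim$matrix, "ctrl-stiff", "ctrl-soft",
                                  floor = floor, threshold = threshold,
                                  min_probes = min_probes)
    sum(calls$status %in% c("up", "down", "bidirectional"))
  }
  base <- n_reg(5, 0.5, 3)
  expect_lte(n_reg(5, 0.8, 3), base)
  expect_lte(n_reg(5, 0.5, 4), base)
  expect_lte(n_reg(6.5, 0.5, 3), base)
})

test_that("knockdown dependence re-extracts the stored probe IDs", {
  calls <- call_genes(data.frame(
    probe_id = sprintf("p%d", 1:4),
    gene_id = rep("gU", 4),
    log2fc = c(0.9, 0.9, 0.9, 0.1)), 0.5, 3)
  # same probes reversed in the knockdown contrast
  kd <- data.frame(probe_id = sprintf("p%d", 1:4),
                   gene_id = rep("gU", 4),
                   log2fc = c(-0.6, -0.6, -0.6, 2.0))
  dep <- assess_gata2_dependence(calls, kd, 0.5)
  expect_true(dep$dependent)
  expect_true(dep$concordant_reversal)
  expect_equal(dep$avg_log2fc_kd, -0.6)  # p4 not among regulated probes

  # a flat knockdown contrast yields no dependence
  kd0 <- transform(kd, log2fc = 0)
  expect_false(assess_gata2_dependence(calls, kd0, 0.5)$dependent)

  # genes whose probes are missing from the contrast stay visible
  kd_miss <- data.frame(probe_id = "x1", gene_id = "gX", log2fc = 1)
  dep2 <- assess_gata2_dependence(calls, kd_miss, 0.5)
  expect_false(dep2$assessable)
  expect_true(is.na(dep2$dependent))
})

test_that("synthetic four-arm recovery: calls and dependence match planted truth", {
  sim <- simulate_probe_matrix(array_sim_config(
    n_genes = 200, effect_log2fc = 1.0, noise_sd = 0.05, seed = 5))
  calls <- call_stiffness_genes(sim$matrix, "ctrl-stiff", "ctrl-soft")
  sets <- regulated_sets(calls)
  tg <- sim$truth$genes
  expect_gte(mean(tg$gene_id[tg$direction == "up"] %in% sets$up), 0.95)
  expect_gte(mean(tg$gene_id[tg$direction == "down"] %in% sets$down), 0.95)

  kd_fcs <- probe_log2fc(
    filter_expressed(sim$matrix, 5, c("ctrl-soft", "kd-soft")),
    "ctrl-soft", "kd-soft")
  dep <- assess_gata2_dependence(calls, kd_fcs)
  truth_dep <- tg$gata2_dependent[match(dep$gene_id, tg$gene_id)]
  expect_gte(mean(dep$dependent == truth_dep, na.rm = TRUE), 0.95)
})

test_that("flat gene-level filter uses strict inequalities", {
  expr <- cbind(a = c(7, 7, 7, 7, 7), b = c(7.6, 7.5, 6.6, 6.2, 7.51))
  rownames(expr) <- sprintf("g%d", 1:5)
  pm <- toy_matrix(expr, conditions = c("static", "OSS"))
  sets <- apply_flat_filter(pm, "static", "OSS", floor = 5, threshold = 0.5)
  expect_setequal(sets$up, c("g1", "g5"))
  expect_setequal(sets$down, "g4")

  null_pm <- toy_matrix(cbind(a = rep(7, 3), b = rep(7.2, 3)),
                        conditions = c("static", "OSS"))
  null_sets <- apply_flat_filter(null_pm, "static", "OSS")
  expect_length(null_sets$up, 0)
  expect_length(null_sets$down, 0)
})

test_that("cross-stimulus overlap counts exact set intersections", {
  a <- list(up = c("g1", "g2", "g3"), down = "g5")
  b <- list(up = c("g2", "g3", "g4"), down = "g5")
  ov <- cross_stimulus_overlap(a, b)
  expect_equal(ov$shared_up, 2)
  expect_equal(ov$shared_down, 1)
  expect_equal(ov$discordant, 0)

  same <- cross_stimulus_overlap(a, a)
  expect_equal(same$shared_up, 3)
  expect_equal(same$shared_down, 1)

  disj <- cross_stimulus_overlap(a, list(up = "x1", down = "x2"))
  expect_equal(disj$shared_up + disj$shared_down + disj$discordant, 0)

  mapped <- cross_stimulus_overlap(a, list(up = "B2", down = character(0)),
                                   id_map = data.frame(from = "B2", to = "g2"))
  expect_equal(mapped$shared_up, 1)
})

test_that("regulated transcription factors are counted by intersection", {
  sets <- list(up = sprintf("g%d", 1:6), down = sprintf("g%d", 7:10))
  expect_equal(count_regulated_tfs(sets, c("g2", "g5", "g99")), 2)
  expect_equal(count_regulated_tfs(sets, c("x1", "x2")), 0)
  expect_warning(n <- count_regulated_tfs(sets, character(0)), "empty")
  expect_equal(n, 0)
})
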