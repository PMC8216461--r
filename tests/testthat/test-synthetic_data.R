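test_that("simulated gene models respect the cassette topology", {
  m <- simulate_gene()
  expect_identical(m$exon_id, cd44_gene_model()$exon_id)
  m2 <- simulate_gene(n_constant_left = 2, n_variant = 3,
                      n_constant_right = 2)
  expect_equal(sum(m2$role == "variant"), 3)
  expect_error(simulate_gene(n_variant = 0), "at least one variant")
  expect_error(simulate_gene(n_constant_left = 0), "flanked")
})

test_that("generators are bit-reproducible given seed and config", {
  m <- cd44_gene_model()
  cfg <- sim_config(seed = 20240916)
  expect_identical(simulate_junction_counts(m, cfg),
                   simulate_junction_counts(m, cfg))
  expect_identical(simulate_methylation(m, cfg),
                   simulate_methylation(m, cfg))
  expect_identical(simulate_qc(20, 0.3, seed = 5),
                   simulate_qc(20, 0.3, seed = 5))
  expect_identical(simulate_event_tables(seed = 3),
                   simulate_event_tables(seed = 3))
  # different seeds give different draws
  cfg2 <- sim_config(seed = 20240917)
  expect_false(identical(simulate_junction_counts(m, cfg)$junctions,
                         simulate_junction_counts(m, cfg2)$junctions))
})

test_that("junction counts realize the logistic coupling model", {
  m <- cd44_gene_model()
  # beta = 0 with equal methylation: groups indistinguishable in
  # expectation; the analytic mixture value is plogis(baseline)
  cfg0 <- sim_config(seed = 20240918, beta = 0, meth_a = 0.5, meth_b = 0.5,
                     depth = 1e4)
  sim0 <- simulate_junction_counts(m, cfg0)
  expect_equal(unname(sim0$truth$expected_inclusion_pct),
               rep(100 * plogis(0), 2))
  ajs <- enumerate_anchor_junctions(sim0$junctions, m, "C5")
  res <- inclusion_percentage(ajs)
  by_group <- split(res$inclusion_pct, sim0$group[res$sample])
  expect_lt(abs(mean(by_group$A) - mean(by_group$B)), 3)
  # strong positive coupling with hypomethylated group A: B includes more
  cfg1 <- sim_config(seed = 20240918, beta = 4, meth_a = 0, meth_b = 1)
  sim1 <- simulate_junction_counts(m, cfg1)
  res1 <- inclusion_percentage(
    enumerate_anchor_junctions(sim1$junctions, m, "C5"))
  by1 <- split(res1$inclusion_pct, sim1$group[res1$sample])
  expect_gt(min(by1$B), max(by1$A))
  # v->v junctions exist and are excluded from the anchor statistic
  cls <- classify_junction(sim1$junctions, m, "C5")
  expect_true(any(cls == "other"))
})

test_that("fitted coupling slope recovers the sign of beta", {
  m <- cd44_gene_model()
  grid <- seq(0.1, 0.9, by = 0.2)
  slope_for <- function(beta, seed) {
    pct <- vapply(seq_along(grid), function(k) {
      cfg <- sim_config(seed = seed + k, beta = beta,
                        meth_a = grid[k], meth_b = grid[k], depth = 5e3)
      sim <- simulate_junction_counts(m, cfg)
      res <- inclusion_percentage(
        enumerate_anchor_junctions(sim$junctions, m, "C5"))
      mean(res$inclusion_pct, na.rm = TRUE)
    }, numeric(1))
    unname(coef(lm(qlogis(pct / 100) ~ grid))[2])
  }
  seeds <- 20240919 + (0:9) * 101
  expect_true(all(sapply(seeds, function(s) slope_for(1.5, s)) > 0))
  expect_lt(slope_for(-1.5, seeds[1]), 0)
})

test_that("methylation bins carry the planted DMR truth", {
  m <- cd44_gene_model()
  cfg_null <- sim_config(seed = 20240920, meth_a = 0.6, meth_b = 0.6)
  sim_null <- simulate_methylation(m, cfg_null)
  expect_equal(nrow(sim_null$true_dmrs), 0)
  cfg <- sim_config(seed = 20240920)   # 0.2 vs 0.8: 4-fold depletion in A
  sim <- simulate_methylation(m, cfg)
  expect_equal(nrow(sim$true_dmrs), 9)             # one bin per variant exon
  expect_identical(unique(sim$true_dmrs$direction), "hypo")
  vex <- m[m$role == "variant", ]
  expect_true(all(sim$true_dmrs$start %in% vex$start))
  expect_equal(dim(sim$counts), c(nrow(sim$roi), 2 * cfg$n_per_group))
})

test_that("SJ-tab writer round-trips through the reader", {
  m <- cd44_gene_model()
  cfg <- sim_config(seed = 20240921, n_per_group = 2)
  sim <- simulate_junction_counts(m, cfg)
  f <- tempfile(fileext = ".tab")
  write_sj_tab(sim$junctions, "A1", f)
  back <- read_junction_table(f, "sj_tab", sample = "A1")
  expect_equal(back$intron_start, sim$junctions$intron_start)
  expect_equal(back$intron_end, sim$junctions$intron_end)
  expect_equal(back$A1, sim$junctions$A1)
})

test_that("planted QC failures are exactly the filter's exclusions", {
  qc0 <- simulate_qc(10, fraction_bad = 0, seed = 1)
  expect_identical(unique(qc_filter(qc0)$status), "kept")
  qc1 <- simulate_qc(10, fraction_bad = 1, seed = 2)
  expect_identical(unique(qc_filter(qc1)$status), "excluded")
  qc <- simulate_qc(26, fraction_bad = 7 / 26, seed = 3)
  res <- qc_filter(qc)
  expect_equal(sum(res$status == "excluded"), 7)
  expect_identical(res$status == "excluded", qc$bad)
})

test_that("sim_config validates its ranges", {
  expect_error(sim_config(depth = 0))
  expect_error(sim_config(nb_dispersion = -1))
  expect_error(sim_config(meth_a = 1.2))
})
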