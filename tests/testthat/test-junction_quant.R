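test_that("sj_tab and bed dialects converge to the same internal record", {
  sj <- tempfile(fileext = ".tab")
  writeLines("chr1\t1001\t1500\t1\t0\t1\t12\t3\t20", sj)
  a <- read_junction_table(sj, "sj_tab", sample = "s1")
  expect_equal(a$intron_start, 1000)
  expect_equal(a$intron_end, 1500)
  expect_equal(a$s1, 12)          # unique reads only, multi-mapped ignored
  expect_identical(a$strand, "+")
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t1000\t1500\tj1\t12\t+", bed)
  b <- read_junction_table(bed, "bed", sample = "s1")
  expect_equal(a, b)
})

test_that("junction reader reports malformed input precisely", {
  f <- tempfile()
  writeLines(c("chr1\t100\t200\t1\t0\t1\t5\t0\t20", "chr1\tbroken"), f)
  expect_error(read_junction_table(f, "sj_tab"), "line 2")
  writeLines("chr1\t100\t200\t1\t0\t1\t-5\t0\t20", f)
  expect_error(read_junction_table(f, "sj_tab"), "negative")
  writeLines(character(0), f)
  expect_warning(out <- read_junction_table(f, "sj_tab"), "empty")
  expect_equal(nrow(out), 0)
})

test_that("junctions classify by anchor involvement and partner exon", {
  m <- cd44_gene_model()
  jx <- toy_junctions(m, c("C5>v3", "C5>C16", "v6>v7", "C4>C5", "C5>v6",
                           "v10>C16", "C16>C17"),
                      counts = rep(1L, 7))
  expect_identical(classify_junction(jx, m, "C5"),
                   c("inclusion", "skipping", "other", "other", "inclusion",
                     "other", "other"))
  # C16 anchored: variant partner = inclusion, far constant = skipping
  expect_identical(classify_junction(jx, m, "C16"),
                   c("other", "skipping", "other", "other", "other",
                     "inclusion", "other"))
  # junction landing in an intron is 'other'
  odd <- tibble::tibble(chrom = "chrS", intron_start = m$end[5],
                        intron_end = m$start[6] - 10, strand = "+", s1 = 3L)
  expect_identical(classify_junction(odd, m, "C5"), "other")
  # wrong-strand junctions do not match; unknown strand does
  jx2 <- toy_junctions(m, "C5>v3", 1L, strand = "-")
  expect_identical(classify_junction(jx2, m, "C5"), "other")
  jx3 <- toy_junctions(m, "C5>v3", 1L, strand = "*")
  expect_identical(classify_junction(jx3, m, "C5"), "inclusion")
})

test_that("per-sample detection filter is applied and monotone", {
  m <- cd44_gene_model()
  counts <- cbind(s1 = c(1L, 10L, 10L), s2 = c(5L, 10L, 10L))
  jx <- toy_junctions(m, c("C5>v3", "C5>v6", "C5>C16"), counts)
  ajs <- enumerate_anchor_junctions(jx, m, "C5", min_reads = 2)
  expect_equal(ajs$s1[1], 0L)   # 1 read: undetected in s1 only
  expect_equal(ajs$s2[1], 5L)
  # min_reads = 1 retains every nonzero junction
  ajs1 <- enumerate_anchor_junctions(jx, m, "C5", min_reads = 1)
  expect_equal(ajs1$s1[1], 1L)
  # raising the threshold never adds detected junctions
  detected <- function(min_reads) {
    a <- enumerate_anchor_junctions(jx, m, "C5", min_reads)
    sum(a$s1 > 0) + sum(a$s2 > 0)
  }
  thresholds <- c(1, 2, 5, 10, 11)
  expect_true(all(diff(vapply(thresholds, detected, numeric(1))) <= 0))
  expect_error(enumerate_anchor_junctions(jx, m, "nope"), "not in gene model")
})

test_that("inclusion percentage matches hand computation and its invariants", {
  m <- cd44_gene_model()
  jx <- toy_junctions(m, c("C5>v3", "C5>v6", "C5>C16"),
                      cbind(s1 = c(10L, 5L, 35L)))
  ajs <- enumerate_anchor_junctions(jx, m, "C5")
  res <- inclusion_percentage(ajs)
  expect_equal(res$inclusion_pct, 30)          # 15 / 50
  expect_equal(res$skipping_pct, 70)
  # all reads on the skipping junction -> 0; equal split -> 50
  jx0 <- toy_junctions(m, c("C5>v3", "C5>C16"), cbind(s1 = c(0L, 40L)))
  expect_equal(inclusion_percentage(
    enumerate_anchor_junctions(jx0, m, "C5"))$inclusion_pct, 0)
  jx50 <- toy_junctions(m, c("C5>v3", "C5>C16"), cbind(s1 = c(20L, 20L)))
  expect_equal(inclusion_percentage(
    enumerate_anchor_junctions(jx50, m, "C5"))$inclusion_pct, 50)
  # junction-weighted mode counts detected junctions once each
  expect_equal(inclusion_percentage(ajs, weight = "junctions")$inclusion_pct,
               100 * 2 / 3)
  # zero denominator is missing, not zero
  jxna <- toy_junctions(m, c("C5>v3", "C5>C16"), cbind(s1 = c(1L, 1L)))
  resna <- inclusion_percentage(enumerate_anchor_junctions(jxna, m, "C5",
                                                           min_reads = 5))
  expect_true(nrow(resna) == 0 || is.na(resna$inclusion_pct))
})

test_that("percentages are invariant to row order and count scaling", {
  m <- cd44_gene_model()
  set.seed(20240902)
  for (rep in 1:5) {
    cnt <- cbind(s1 = rpois(10, 40) + 2L, s2 = rpois(10, 40) + 2L)
    spec <- c(paste0("C5>v", 2:10), "C5>C16")
    jx <- toy_junctions(m, spec, cnt)
    ajs <- enumerate_anchor_junctions(jx, m, "C5")
    base <- inclusion_percentage(ajs)
    expect_equal(base$inclusion_pct + base$skipping_pct, c(100, 100),
                 tolerance = 1e-9)
    perm <- jx[sample(nrow(jx)), ]
    expect_equal(inclusion_percentage(
      enumerate_anchor_junctions(perm, m, "C5"))$inclusion_pct,
      base$inclusion_pct)
    scaled <- jx
    scaled$s1 <- scaled$s1 * 7L; scaled$s2 <- scaled$s2 * 7L
    expect_equal(inclusion_percentage(
      enumerate_anchor_junctions(scaled, m, "C5"))$inclusion_pct,
      base$inclusion_pct)
  }
})

test_that("estimated inclusion converges to the simulator's mixture value", {
  m <- cd44_gene_model()
  cfg <- sim_config(seed = 20240903, depth = 1e4, beta = 2)
  sim <- simulate_junction_counts(m, cfg)
  ajs <- enumerate_anchor_junctions(sim$junctions, m, "C5")
  res <- inclusion_percentage(ajs)
  by_group <- split(res$inclusion_pct, sim$group[res$sample])
  expected <- sim$truth$expected_inclusion_pct
  expect_equal(mean(by_group$A), expected[["A"]], tolerance = 0.03)
  expect_equal(mean(by_group$B), expected[["B"]], tolerance = 0.03)
})

test_that("group comparisons handle paired tests and degenerate input", {
  x <- c(10, 12, 14, 16, 18)
  expect_warning(res <- compare_inclusion(x, x, "paired",
                                          "wilcoxon_signed_rank"),
                 "zero")
  expect_equal(res$p.value, 1)
  expect_warning(res2 <- compare_inclusion(c(2, 3), c(1, 2), "paired", "t"),
                 "degenerate")
  expect_true(is.na(res2$p.value))
  expect_error(compare_inclusion(c(1), c(2), "paired", "t"), "at least 2")
  expect_error(compare_inclusion(x, x, "unpaired", "wilcoxon_signed_rank"),
               "paired")
  # unpaired t on clearly separated groups
  res3 <- compare_inclusion(c(10, 11, 12), c(30, 31, 32), "unpaired", "t")
  expect_lt(res3$p.value, 0.01)
})

test_that("exact signed-rank p equals full sign enumeration", {
  set.seed(20240904)
  for (n in c(5, 6, 8)) {
    for (rep in 1:4) {
      x <- round(runif(n, 10, 90), 3)
      y <- x + round(runif(n, -20, 30), 4)
      for (alt in c("two.sided", "greater", "less")) {
        got <- compare_inclusion(x, y, "paired", "wilcoxon_signed_rank",
                                 alternative = alt)
        expect_equal(got$p.value, oracle_wilcoxon_exact(x - y, alt),
                     tolerance = 1e-12,
                     label = paste("n", n, "alt", alt))
      }
    }
  }
})
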