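mk_event <- function(gene, src, tgt, dpsi, kind = "cassette",
                     chrom = "chrE") {
  tibble::tibble(gene = gene, chrom = chrom, source_site = src,
                 target_site = tgt, kind = kind, dpsi = dpsi,
                 confidence = 0.99)
}

mk_dmr <- function(start, end, log2fc, significant = TRUE,
                   chrom = "chrE") {
  tibble::tibble(chrom = chrom, start = start, end = end, log2fc = log2fc,
                 p_raw = 1e-4, p_adj = if (significant) 1e-3 else 0.6,
                 direction = ifelse(log2fc < 0, "hypo", "hyper"),
                 significant = significant)
}

test_that("event matching requires a shared site and picks the best pair", {
  e1 <- mk_event("G1", 100, 500, -0.3)
  # identical event matches
  m <- match_events(e1, e1)
  expect_equal(nrow(m$pairs), 1)
  expect_equal(m$pairs$n_shared, 2)
  # same gene, no shared site: unmatched
  m2 <- match_events(e1, mk_event("G1", 900, 1500, -0.3))
  expect_equal(nrow(m2$pairs), 0)
  expect_equal(nrow(m2$unmatched1), 1)
  # one shared site with a different far site still matches
  m3 <- match_events(e1, mk_event("G1", 100, 900, -0.3))
  expect_equal(nrow(m3$pairs), 1)
  expect_identical(classify_event_pair(m3$pairs), "different_event")
  # a gene contributes one pair: most shared sites, then smallest span
  e2 <- rbind(mk_event("G1", 100, 900, -0.3),   # 1 shared site
              mk_event("G1", 100, 500, 0.4))    # 2 shared sites
  m4 <- match_events(e1, e2)
  expect_equal(nrow(m4$pairs), 1)
  expect_equal(m4$pairs$dpsi_2, 0.4)
  e3 <- rbind(mk_event("G1", 100, 2000, -0.3),  # 1 shared, span 1900
              mk_event("G1", 100, 900, -0.2))   # 1 shared, span 800
  m5 <- match_events(e1, e3)
  expect_equal(m5$pairs$target_2, 900)
  # tolerance admits near-misses
  m6 <- match_events(e1, mk_event("G1", 102, 498, -0.3), site_tolerance = 5)
  expect_equal(nrow(m6$pairs), 1)
  expect_identical(classify_event_pair(m6$pairs, site_tolerance = 5),
                   "same_local")
})

test_that("structural pair classes follow kind and site agreement", {
  p_same <- match_events(mk_event("G", 1, 9, 0.5),
                         mk_event("G", 1, 9, 0.5))$pairs
  expect_identical(classify_event_pair(p_same), "same_local")
  p_alt <- match_events(mk_event("G", 1, 9, 0.5),
                        mk_event("G", 1, 9, 0.5, kind = "alt_promoter"))$pairs
  expect_identical(classify_event_pair(p_alt), "alt_promoter")
})

test_that("DMR proximity windows are symmetric around the site span", {
  ev <- mk_event("G", 1000, 3000, -0.4)
  on_exon <- mk_dmr(1500, 2500, -1)
  expect_equal(nrow(dmr_proximity(ev, on_exon, window = 0)), 1)
  far <- mk_dmr(13000, 13500, -1)      # 10 kb beyond the span
  expect_equal(nrow(dmr_proximity(ev, far, window = 5000)), 0)
  expect_equal(nrow(dmr_proximity(ev, far, window = 1e7)), 1)
  other_chrom <- mk_dmr(1500, 2500, -1, chrom = "chrX")
  expect_equal(nrow(dmr_proximity(ev, other_chrom, window = 5000)), 0)
})

test_that("direction concordance follows the sign convention", {
  ev <- mk_event("G", 1000, 3000, -0.4)
  hypo <- mk_dmr(1500, 2500, -1)
  hyper <- mk_dmr(1500, 2500, 1)
  cat1 <- concordance_category(-0.4, -0.3, hypo, hypo, ev, ev)
  expect_identical(cat1, "concordant")     # less methylation, less inclusion
  expect_identical(concordance_category(-0.4, -0.3, hyper, hyper, ev, ev),
                   "opposite")
  expect_identical(concordance_category(0.4, 0.3, hyper, hyper, ev, ev),
                   "concordant")
  expect_identical(concordance_category(-0.4, -0.3, NULL, NULL, ev, ev),
                   "meDNA_absent")
  # mixed signs between systems
  expect_identical(concordance_category(-0.4, -0.3, hypo, hyper, ev, ev),
                   "uncertain")
  # matched but non-significant DMRs
  ns <- mk_dmr(1500, 2500, -1, significant = FALSE)
  expect_identical(concordance_category(-0.4, -0.3, ns, ns, ev, ev),
                   "uncertain")
  # conflicting significant DMRs within one system
  conflict <- rbind(mk_dmr(1500, 2500, -1), mk_dmr(2600, 2900, 2))
  expect_identical(concordance_category(-0.4, -0.3, conflict, hypo, ev, ev),
                   "uncertain")
  # zero dpsi cannot be signed
  expect_identical(concordance_category(0, -0.3, hypo, hypo, ev, ev),
                   "uncertain")
  # either-system mode uses the available direction
  expect_identical(concordance_category(-0.4, -0.3, hypo, ns, ev, ev,
                                        require = "either"), "concordant")
  # label swap with equal signs leaves the category unchanged
  expect_identical(concordance_category(-0.3, -0.4, hypo, hypo, ev, ev), cat1)
})

test_that("nearest significant DMR decides among multiple matches", {
  ev <- mk_event("G", 1000, 3000, -0.4)
  near_hypo <- mk_dmr(1900, 2100, -1)        # centered on the span
  far_hyper_ns <- mk_dmr(6000, 6500, 2, significant = FALSE)
  dmrs <- rbind(near_hypo, far_hyper_ns)
  expect_identical(concordance_category(-0.4, -0.4, dmrs, near_hypo, ev, ev),
                   "concordant")
})

test_that("tallies partition the records and derive the printed fractions", {
  sim <- simulate_event_tables(seed = 20240914)
  records <- classify_concordance(sim$events1, sim$events2,
                                  sim$dmrs1, sim$dmrs2)
  # classifier recovers every planted category
  merged <- merge(records, sim$truth, by = "gene")
  expect_identical(merged$category.x, merged$category.y)
  expect_equal(nrow(records), 63)
  tal <- tally_categories(records)
  expect_equal(sum(tal$counts), nrow(records))   # partition
  expect_equal(tal$same_local, 49)
  expect_equal(tal$dmr_proximal, 41)
  expect_equal(tal$counts[["concordant"]], 24)
  expect_equal(tal$counts[["opposite"]], 12)
  expect_equal(tal$pct_concordant_of_proximal, 100 * 24 / 41)
  # empty input: zero counts, undefined percentages
  tal0 <- tally_categories(records[0, ])
  expect_equal(sum(tal0$counts), 0)
  expect_true(is.na(tal0$pct_dmr_proximal))
  # all concordant
  talc <- tally_categories(records[records$category == "concordant", ])
  expect_equal(talc$pct_concordant_of_proximal, 100)
})

test_that("random compositions always partition and agree with truth", {
  set.seed(20240915)
  for (rep in 1:3) {
    comp <- c(concordant = sample(3:20, 1), opposite = sample(3:15, 1),
              uncertain = sample(2:8, 1), meDNA_absent = sample(2:8, 1),
              alt_promoter = sample(2:8, 1), different_event = sample(2:8, 1))
    sim <- simulate_event_tables(comp, seed = 100 + rep)
    records <- classify_concordance(sim$events1, sim$events2,
                                    sim$dmrs1, sim$dmrs2)
    expect_equal(nrow(records), sum(comp))
    got <- records$category[match(sim$truth$gene, records$gene)]
    expect_identical(got, sim$truth$category)
    expect_equal(sum(tally_categories(records)$counts), sum(comp))
  }
})
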