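test_that("allele frequency arithmetic and missing handling", {
  rec <- mk_records(af_mut = c(1, 1/3, NA), dp_mut = c(30, 30, 50))
  af <- compute_af(rec, "mutant")
  expect_equal(af$af, c(1, 1/3, NA_real_))
  expect_equal(af$depth_used, c(30L, 30L, 0L))
  expect_error(compute_af(rec, "nosuchpool"), "unknown pool")
})

test_that("quality filters drop on AF, depth and GQ with fixed attribution", {
  rec <- mk_records(
    af_mut = c(1.0, 4 / 9, 1.0, 0.30, 1.0, 0.2),
    dp_mut = c(50, 9, 50, 50, 50, 5),
    gq_mut = c(99, 99, 29, 99, 99, 10)
  )
  out <- apply_quality_filters(rec, filter_config())
  expect_equal(nrow(out$retained), 2L)
  expect_equal(out$retained$pos, c(1000L, 5000L))
  # row 2: depth 9 < 10; row 3: GQ 29 < 30; row 4: AF 0.30 inclusive;
  # row 6 fails AF and depth and GQ but is attributed to AF (first rule)
  expect_equal(out$drop_counts, c(af = 2L, depth = 1L, gq = 1L))
  expect_equal(out$n_input, 6L)
})

test_that("filtering is order-independent", {
  set.seed(91)
  rec <- mk_records(af_mut = runif(40), dp_mut = sample(5:60, 40, TRUE),
                    gq_mut = sample(10:99, 40, TRUE))
  perm <- sample(nrow(rec))
  shuffled <- bsamap:::subset_variants(rec, perm)
  a <- apply_quality_filters(rec)$retained
  b <- apply_quality_filters(shuffled)$retained
  expect_setequal(a$pos, b$pos)
})

test_that("candidate selection implements the association signature", {
  rec <- mk_records(af_mut = c(1.0, 1.0, 0.98, 1.0, 1.0),
                    af_az = c(1 / 3, 0.60, 1 / 3, 0.49, NA),
                    af_wt = c(0, 0, 0, 0.2, 0))
  keep0 <- select_candidates(rec, filter_config())
  # kept: the causal signature (1.0, 0.33, 0) and (1.0, 0.49, ...) minus
  # the wild-type-contaminated row; azygous-missing rows drop by default
  expect_equal(keep0$pos, c(1000L))
  cfg_tol <- filter_config(mutant_af_tolerance = 0.05)
  expect_true(3000L %in% select_candidates(rec, cfg_tol)$pos)
  cfg_keep <- filter_config(azygous_missing = "keep")
  expect_true(5000L %in% select_candidates(rec, cfg_keep)$pos)
  cfg_nowt <- filter_config(require_absent_in_wildtype = FALSE)
  expect_true(4000L %in% select_candidates(rec, cfg_nowt)$pos)
})

test_that("selection is monotone in its thresholds and nested in the quality filter", {
  set.seed(17)
  n <- 60
  rec <- mk_records(af_mut = sample(c(1, 0.97, runif(8)), n, TRUE),
                    af_az = runif(n, 0, 0.7),
                    af_wt = sample(c(0, 0, 0, 0.05), n, TRUE),
                    dp_mut = sample(5:60, n, TRUE),
                    gq_mut = sample(20:99, n, TRUE))
  strict <- filter_config()
  loose <- filter_config(mutant_af_tolerance = 0.05, azygous_af_max = 0.6,
                         wildtype_af_max = 0.1)
  qf <- apply_quality_filters(rec, strict)
  cand_strict <- select_candidates(qf$retained, strict)
  cand_loose <- select_candidates(qf$retained, loose)
  expect_true(all(cand_strict$pos %in% cand_loose$pos))
  expect_true(all(cand_strict$pos %in% qf$retained$pos))
})

test_that("linkage consistency scores the neighbourhood", {
  rec <- mk_records(af_mut = c(1, 1, 1, 1, 1, 1),
                    pos = c(1000L, 1100L, 1200L, 1300L, 1400L, 1500L))
  expect_equal(
    linkage_consistency(rec, "chr1", 1200L, window_bp = 1000), 1.0)
  rec2 <- mk_records(af_mut = c(0.9, 0.85, 0.5, 0.4, 1),
                     pos = c(1000L, 1100L, 1300L, 1400L, 1200L))
  expect_equal(
    linkage_consistency(rec2, "chr1", 1200L, window_bp = 1000,
                        min_neighbors = 3), 0.5)
  expect_true(is.na(
    linkage_consistency(rec2, "chr1", 1200L, window_bp = 50,
                        min_neighbors = 3)))
})

test_that("the planted causal variant survives both filter stages under clean conditions", {
  ref <- generate_reference(n_chrom = 1, lengths = 2e5, seed = 51,
                            genes_per_chrom = 3, cds_codons_range = c(40, 60))
  design <- cross_design(misclassification = 0, seq_error = 0)
  ok <- 0L
  for (s in 1:20) {
    muts <- induce_mutations(ref$genome, ref$genes, n_mutations = 40,
                             seed = 500 + s)
    pop <- breed_bc1f2(design, muts, ref$genome, seed = 600 + s)
    pools <- make_pools(pop, design)
    rec <- simulate_pool_reads(pools, design, seed = 700 + s)
    qf <- apply_quality_filters(rec, filter_config())
    cand <- select_candidates(qf$retained, filter_config())
    ca <- attr(muts, "causal")
    if (any(cand$chrom == ca$chrom & cand$pos == ca$pos)) ok <- ok + 1L
  }
  expect_gte(ok, 19L)
})
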