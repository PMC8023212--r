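test_that("reference generation is seed-deterministic and emits valid CDSs", {
  r1 <- generate_reference(n_chrom = 1, lengths = 1e5, seed = 7,
                           genes_per_chrom = 4, cds_codons_range = c(50, 80))
  r2 <- generate_reference(n_chrom = 1, lengths = 1e5, seed = 7,
                           genes_per_chrom = 4, cds_codons_range = c(50, 80))
  expect_identical(as.character(r1$genome), as.character(r2$genome))
  expect_identical(r1$genes, r2$genes)
  for (g in r1$genes) {
    p <- translate_cds(spliced_cds(g, r1$genome))
    expect_equal(substr(p, 1, 1), "M")
    expect_equal(substr(p, nchar(p), nchar(p)), "*")
    expect_false(grepl("*", substr(p, 1, nchar(p) - 1), fixed = TRUE))
  }
})

test_that("generated reference round-trips through FASTA and GFF3", {
  ref <- generate_reference(n_chrom = 2, lengths = c(5e4, 5e4), seed = 3,
                            genes_per_chrom = 3,
                            cds_codons_range = c(40, 60))
  fa <- withr::local_tempfile(fileext = ".fasta")
  gf <- withr::local_tempfile(fileext = ".gff3")
  write_fasta(ref$genome, fa)
  write_gff3(ref$genes, gf)
  g2 <- read_fasta(fa)
  expect_equal(length(g2), 2L)
  expect_equal(as.character(g2), as.character(ref$genome))
  expect_length(read_gff3(gf), length(ref$genes))
})

test_that("induced mutations respect the transition bias and the forced causal codon", {
  ref <- generate_reference(n_chrom = 1, lengths = 1e5, seed = 2,
                            genes_per_chrom = 4, cds_codons_range = c(50, 80))
  muts <- induce_mutations(ref$genome, ref$genes, n_mutations = 40,
                           transition_fraction = 1, seed = 4)
  expect_equal(sum(muts$is_causal), 1L)
  expect_false(anyDuplicated(paste(muts$chrom, muts$pos)) > 0)
  trans <- paste0(muts$ref, muts$alt) %in% c("AG", "GA", "CT", "TC")
  expect_true(all(trans))

  # causal: codon position 1 of a CTC/CTT leucine codon, C->T, Leu->Phe
  ca <- attr(muts, "causal")
  gene <- Filter(function(g) g$gene_id == ca$gene_id, ref$genes)[[1]]
  row <- muts[muts$is_causal, ]
  ann <- annotate_effect(row$chrom, row$pos, row$ref, row$alt, gene,
                         ref$genome)
  expect_true(ann$codon_ref %in% c("CTC", "CTT"))
  expect_equal(substr(ann$codon_alt, 1, 1), "T")
  expect_equal(ann$aa_ref, "L")
  expect_equal(ann$aa_alt, "F")
  expect_equal(ann$effect_class, "missense")
  expect_equal(ann$aa_pos, ca$aa_pos)
})

test_that("empirical transition fraction matches the configured rate", {
  ref <- generate_reference(n_chrom = 1, lengths = 1e5, seed = 11,
                            genes_per_chrom = 4, cds_codons_range = c(80, 120))
  muts <- induce_mutations(ref$genome, ref$genes, n_mutations = 10000,
                           transition_fraction = 0.9, seed = 12)
  bg <- muts[!muts$is_causal, ]
  obs <- mean(paste0(bg$ref, bg$alt) %in% c("AG", "GA", "CT", "TC"))
  # binomial sampling oracle: 3 sigma around the configured fraction
  tol <- 3 * sqrt(0.9 * 0.1 / nrow(bg))
  expect_lt(abs(obs - 0.9), tol)
})

test_that("zero recombination gives perfect within-chromosome linkage", {
  ref <- generate_reference(n_chrom = 2, lengths = 5e4, seed = 6,
                            genes_per_chrom = 2, cds_codons_range = c(40, 50))
  muts <- induce_mutations(ref$genome, ref$genes, n_mutations = 30, seed = 8)
  design <- cross_design(recomb_rate = 0, misclassification = 0)
  pop <- breed_bc1f2(design, muts, ref$genome, seed = 9)
  for (ch in unique(muts$chrom)) {
    idx <- which(muts$chrom == ch)
    rng <- apply(pop$dosage[, idx, drop = FALSE], 1, function(x) diff(range(x)))
    expect_true(all(rng == 0))
  }
})

test_that("segregation and unlinked-site allele frequency follow Mendel", {
  ref <- generate_reference(n_chrom = 2, lengths = 5e4, seed = 21,
                            genes_per_chrom = 2, cds_codons_range = c(40, 50))
  muts <- induce_mutations(ref$genome, ref$genes, n_mutations = 10, seed = 22)
  design <- cross_design(misclassification = 0)
  fr_mut <- numeric(50)
  fr_unlinked <- numeric(50)
  unlinked <- which(muts$chrom != muts$chrom[muts$is_causal])[1]
  for (s in seq_len(50)) {
    pop <- breed_bc1f2(design, muts, ref$genome, seed = 100 + s)
    fr_mut[s] <- mean(pop$phenotype == "mutant")
    fr_unlinked[s] <- mean(pop$dosage[, unlinked]) / 2
  }
  n_tot <- 50 * design$n_population
  expect_lt(abs(mean(fr_mut) - 0.25), 3 * sqrt(0.25 * 0.75 / n_tot))
  # mutant-line allele frequency at an unlinked site ~ 1/2
  expect_lt(abs(mean(fr_unlinked) - 0.5), 3 * sqrt(0.25 / n_tot))
})

test_that("pools have the designed sizes and clean composition", {
  ref <- generate_reference(n_chrom = 1, lengths = 5e4, seed = 31,
                            genes_per_chrom = 2, cds_codons_range = c(40, 50))
  muts <- induce_mutations(ref$genome, ref$genes, n_mutations = 10, seed = 32)
  design <- cross_design(misclassification = 0)
  pop <- breed_bc1f2(design, muts, ref$genome, seed = 33)
  pools <- make_pools(pop, design)
  expect_length(pools$members$mutant, 45L)
  expect_length(pools$members$azygous, 54L)
  expect_equal(unname(pools$sizes[["wildtype"]]), 50L)
  # azygous pool holds no causal homozygote when phenotyping is perfect
  expect_true(all(pop$dosage[pools$members$azygous, pop$causal_index] < 2))
  # the wild-type pool carries zero mutant-line alleles everywhere
  expect_true(all(pools$fractions["wildtype", ] == 0))
  # insufficient class counts raise an actionable error
  tiny <- cross_design(n_population = 120, misclassification = 0)
  pop2 <- breed_bc1f2(tiny, muts, ref$genome, seed = 34)
  expect_error(make_pools(pop2, tiny), "n_population")
})

test_that("pooled reads are exact at fixed sites and seed-reproducible", {
  ref <- generate_reference(n_chrom = 1, lengths = 5e4, seed = 41,
                            genes_per_chrom = 2, cds_codons_range = c(40, 50))
  muts <- induce_mutations(ref$genome, ref$genes, n_mutations = 20, seed = 42)
  design <- cross_design(misclassification = 0, seq_error = 0)
  pop <- breed_bc1f2(design, muts, ref$genome, seed = 43)
  pools <- make_pools(pop, design)
  rec <- simulate_pool_reads(pools, design, seed = 44)
  # dosage fraction 1 with no sequencing error: every read carries alt
  fixed <- which(pools$fractions["mutant", ] == 1)
  expect_gt(length(fixed), 0)
  expect_equal(pool_field(rec, "mutant", "ad_alt")[fixed],
               pool_field(rec, "mutant", "dp")[fixed])
  expect_true(all(pool_field(rec, "wildtype", "ad_alt") == 0))

  # same seed => bit-identical VCF
  rec2 <- simulate_pool_reads(pools, design, seed = 44)
  f1 <- withr::local_tempfile(fileext = ".vcf")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(rec, f1, genome = ref$genome)
  write_vcf(rec2, f2, genome = ref$genome)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("pooled call GQ scales with depth and flags uninformative sites", {
  gl <- genotype_call(ad_alt = c(10L, 50L, 0L, 17L), dp = c(10L, 50L, 0L, 50L),
                      seq_error = 0.001)
  expect_equal(gl$gt, c("1/1", "1/1", "./.", "0/1"))
  # homozygous-call confidence is ~3 Phred per supporting read
  expect_gte(gl$gq[1], 30)
  expect_lt(gl$gq[1], 35)
  expect_equal(gl$gq[2], 99L)
  expect_equal(gl$gq[3], 0L)
})
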