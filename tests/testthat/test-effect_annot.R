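test_that("hard-coded codon table matches the published standard code", {
  gc <- Biostrings::GENETIC_CODE
  attr(gc, "alt_init_codons") <- NULL
  expect_equal(sort(names(CODON_TABLE)), sort(names(gc)))
  expect_equal(CODON_TABLE[names(gc)], gc)
})

test_that("variants are located as intergenic, intronic or CDS", {
  toy <- toy_plus_gene()
  expect_length(locate_variant("chr1", 20L, list(toy$gene)), 0L)
  expect_length(locate_variant("chr1", 30L, list(toy$gene)), 0L)
  ctx <- locate_variant("chr1", 21L, list(toy$gene))
  expect_equal(ctx[[1]]$type, "cds")
  expect_equal(ctx[[1]]$cds_offset, 0L)

  two_exon <- gene_model("g2", "chr1", "+",
                         data.frame(start = c(21L, 40L), end = c(26L, 45L)),
                         phases = c(0L, 0L))
  mid <- locate_variant("chr1", 33L, list(two_exon))
  expect_equal(mid[[1]]$type, "intronic")

  # minus strand: the genomic last base of the CDS is translation offset 0
  minus <- toy_minus_gene()
  ctx_m <- locate_variant("chr1", 29L, list(minus$gene))
  expect_equal(ctx_m[[1]]$cds_offset, 0L)
})

test_that("codon consequences on the plus strand", {
  toy <- toy_plus_gene()
  # CTC -> TTC: Leu -> Phe missense at residue 2
  ann <- annotate_effect("chr1", 24L, "C", "T", toy$gene, toy$genome)
  expect_equal(ann$codon_change, "CTC>TTC")
  expect_equal(ann$aa_change, "L2F")
  expect_equal(ann$effect_class, "missense")
  # third codon base: CTC -> CTT synonymous
  syn <- annotate_effect("chr1", 26L, "C", "T", toy$gene, toy$genome)
  expect_equal(syn$codon_change, "CTC>CTT")
  expect_equal(syn$effect_class, "synonymous")
  # start and stop classes
  sl <- annotate_effect("chr1", 23L, "G", "A", toy$gene, toy$genome)
  expect_equal(sl$effect_class, "start_loss")
  stl <- annotate_effect("chr1", 27L, "T", "C", toy$gene, toy$genome)
  expect_equal(stl$effect_class, "stop_loss")
  # reference disagreement signals a coordinate bug
  expect_error(annotate_effect("chr1", 24L, "G", "T", toy$gene, toy$genome),
               "reference mismatch")
})

test_that("minus-strand genes give the identical coding annotation", {
  minus <- toy_minus_gene()
  # CDS is ATG CTC TGA read from position 29 leftwards; the causal
  # C->T change in coding orientation is genomic G->A at position 26
  expect_equal(spliced_cds(minus$gene, minus$genome), "ATGCTCTGA")
  ann <- annotate_effect("chr1", 26L, "G", "A", minus$gene, minus$genome)
  expect_equal(ann$codon_change, "CTC>TTC")
  expect_equal(ann$aa_change, "L2F")
  expect_equal(ann$effect_class, "missense")
})

test_that("nonsense changes are detected", {
  # ATG TGG TGA: TGG -> TGA by G->A at the codon's third base
  s <- paste0(strrep("A", 10), "ATGTGGTGA", strrep("C", 10))
  genome <- Biostrings::DNAStringSet(c(chr1 = s))
  gene <- gene_model("g1", "chr1", "+",
                     data.frame(start = 11L, end = 19L), phases = 0L)
  ann <- annotate_effect("chr1", 16L, "G", "A", gene, genome)
  expect_equal(ann$effect_class, "nonsense")
  expect_equal(ann$aa_change, "W2*")
})

test_that("annotation agrees with the mutate-translate-diff oracle", {
  ref <- generate_reference(n_chrom = 2, lengths = 3e4, seed = 77,
                            genes_per_chrom = 3, cds_codons_range = c(40, 80))
  chrom_seqs <- as.character(ref$genome)
  set.seed(78)
  n_checked <- 0L
  for (g in ref$genes) {
    s <- chrom_seqs[[g$chrom]]
    cds_pos <- unlist(Map(seq.int, g$segments$start, g$segments$end))
    pick <- sample(cds_pos, 40L)
    for (pos in pick) {
      refb <- substr(s, pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
      got <- annotate_effect(g$chrom, pos, refb, alt, g, ref$genome)
      want <- oracle_effect(s, pos, alt, g)
      expect_equal(got$effect_class, want$effect_class,
                   info = sprintf("%s:%d %s>%s", g$chrom, pos, refb, alt))
      if (want$effect_class != "synonymous") {
        expect_equal(got$aa_pos, want$aa_pos)
        expect_equal(got$aa_ref, want$aa_ref)
        expect_equal(got$aa_alt, want$aa_alt)
      }
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 200L)
})

test_that("candidates are prioritized by severity, linkage, position", {
  toy <- toy_plus_gene()
  rec <- mk_records(af_mut = rep(1, 3), pos = c(5L, 24L, 26L))
  rec$linkage_score <- c(1.0, 0.9, 0.9)
  ann <- annotate_candidates(rec, list(toy$gene), toy$genome)
  expect_equal(ann$effect_class, c("missense", "synonymous", "intergenic"))
  expect_equal(ann$pos[1], 24L)

  empty <- annotate_candidates(mk_records(af_mut = numeric(0),
                                          pos = integer(0)),
                               list(toy$gene), toy$genome)
  expect_equal(nrow(empty), 0L)

  # severity ties resolve by linkage score, then position
  rec2 <- mk_records(af_mut = rep(1, 2), pos = c(24L, 45L),
                     chrom = "chr1")
  rec2$linkage_score <- c(0.5, 0.9)
  g2 <- gene_model("g2", "chr1", "+",
                   data.frame(start = 42L, end = 50L), phases = 0L)
  genome2 <- Biostrings::DNAStringSet(c(
    chr1 = paste0(substr(as.character(toy$genome[[1]]), 1, 41),
                  "ATGCTCTGA", strrep("A", 10))))
  ann2 <- annotate_candidates(rec2, list(toy$gene, g2), genome2)
  expect_equal(ann2$pos, c(45L, 24L))
})
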