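# Synthetic forward-genetics experiment: a mutagenized line carrying one
# recessive causal coding SNP plus a genome-wide set of induced,
# transition-biased SNPs; a backcross to wild type followed by selfing
# (BC1F2); phenotype selection into a homozygous-mutant pool and an
# azygous pool; and pooled short-read evidence at every induced site.
#
# Randomness: every operation takes an explicit seed and draws from a
# single generator seeded on entry.  Stream order is fixed and
# documented per operation, so equal seeds give bit-identical output.

#' Describe the genetic experiment
#'
#' Defaults follow the study design the package emulates: a BC1F2
#' population of 300 plants, a homozygous-mutant pool of 45, an azygous
#' (phenotypically wild-type segregant) pool of 54, a wild-type pool of
#' 50, and 45-65x pooled coverage.
#'
#' @param n_population BC1F2 population size.
#' @param pool_sizes Named vector `c(mutant=, azygous=, wildtype=)`.
#' @param coverage_range Range of mean per-pool per-site read depth.
#' @param recomb_rate Expected crossovers per chromosome per meiosis
#'   (Morgans; Haldane model, no interference).
#' @param seq_error Per-read allele miscall probability.
#' @param misclassification Probability that an individual's phenotype
#'   label is flipped during visual/fluorescence screening.
#' @param fvfm_wt,fvfm_mut Mean and sd of the phenotype-conditional
#'   Fv/Fm distributions (normal truncated to (0,1)).
#' @return An object of class `cross_design`.
#' @export
cross_design <- function(n_population = 300L,
                         pool_sizes = c(mutant = 45L, azygous = 54L,
                                        wildtype = 50L),
                         coverage_range = c(45, 65),
                         recomb_rate = 1.0,
                         seq_error = 0.001,
                         misclassification = 0.01,
                         fvfm_wt = c(mean = 0.69, sd = 0.05),
                         fvfm_mut = c(mean = 0.45, sd = 0.07)) {
  stopifnot(n_population >= 1,
            all(c("mutant", "azygous", "wildtype") %in% names(pool_sizes)),
            length(coverage_range) == 2L,
            coverage_range[1] > 0, coverage_range[2] >= coverage_range[1],
            recomb_rate >= 0, seq_error >= 0, seq_error < 0.5,
            misclassification >= 0, misclassification <= 1)
  if (pool_sizes[["mutant"]] + pool_sizes[["azygous"]] > n_population) {
    stop("pool sizes exceed the population size")
  }
  structure(
    list(n_population = as.integer(n_population),
         pool_sizes = vapply(pool_sizes, as.integer, integer(1)),
         coverage_range = as.numeric(coverage_range),
         recomb_rate = recomb_rate, seq_error = seq_error,
         misclassification = misclassification,
         fvfm_wt = fvfm_wt, fvfm_mut = fvfm_mut),
    class = "cross_design"
  )
}

#' Generate a toy reference genome with valid gene models
#'
#' Chromosome sequences are i.i.d. uniform ACGT.  Each chromosome
#' carries `genes_per_chrom` non-overlapping genes (1-3 exons, random
#' strand) whose spliced CDS starts with ATG, ends with a stop codon and
#' contains no internal stop, so every emitted model translates to
#' `Met...Stop`.
#'
#' @param n_chrom Number of chromosomes.
#' @param lengths Chromosome lengths in bp (recycled; each >= 10 kb).
#' @param seed Integer seed.
#' @param genes_per_chrom Genes per chromosome.
#' @param cds_codons_range Range of internal codon counts per gene.
#' @param exons_range Range of exon counts per gene.
#' @param intron_length_range Range of intron lengths (bp).
#' @return `list(genome = DNAStringSet, genes = list of gene_model)`.
#' @export
generate_reference <- function(n_chrom = 2L, lengths = 5e6, seed = 1L,
                               genes_per_chrom = 12L,
                               cds_codons_range = c(150L, 300L),
                               exons_range = c(1L, 3L),
                               intron_length_range = c(80L, 400L)) {
  set.seed(seed)
  lengths <- as.integer(rep_len(lengths, n_chrom))
  if (any(lengths < 1e4)) stop("chromosome lengths must be >= 10 kb")
  bases <- c("A", "C", "G", "T")
  sense <- setdiff(names(CODON_TABLE), STOP_CODONS)
  genes <- list()
  seqs <- character(n_chrom)
  nms <- paste0("chr", seq_len(n_chrom))
  base_codes <- utf8ToInt("ACGT")
  for (ci in seq_len(n_chrom)) {
    L <- lengths[ci]
    s <- intToUtf8(base_codes[sample.int(4L, L, replace = TRUE)])
    placed <- data.frame(start = integer(0), end = integer(0))
    inserts <- list()
    for (gi in seq_len(genes_per_chrom)) {
      n_cod <- sample(cds_codons_range[1]:cds_codons_range[2], 1L)
      n_ex <- sample(exons_range[1]:exons_range[2], 1L)
      cds_len <- 3L * (n_cod + 2L)  # ATG + internal codons + stop
      parts <- if (n_ex == 1L) cds_len else {
        cuts <- sort(sample(cds_len - 1L, n_ex - 1L))
        diff(c(0L, cuts, cds_len))
      }
      introns <- if (n_ex == 1L) integer(0) else {
        sample(intron_length_range[1]:intron_length_range[2], n_ex - 1L,
               replace = TRUE)
      }
      span <- cds_len + sum(introns)
      if (span + 2000L >= L) stop("requested gene longer than chromosome")
      start <- NA_integer_
      for (try in seq_len(200L)) {
        cand <- sample.int(L - span - 2000L, 1L) + 1000L
        if (!any(cand <= placed$end + 100L &
                 cand + span - 1L >= placed$start - 100L)) {
          start <- cand
          break
        }
      }
      if (is.na(start)) stop("could not place gene ", gi, " on ", nms[ci],
                             "; reduce genes_per_chrom or enlarge genome")
      cds <- paste(c("ATG", sample(sense, n_cod, replace = TRUE),
                     sample(STOP_CODONS, 1L)), collapse = "")
      strand <- sample(c("+", "-"), 1L)
      # genomic-order exon lengths; translation order is reversed on '-'
      glens <- if (strand == "+") parts else rev(parts)
      ins <- if (strand == "+") cds else revcomp(cds)
      seg_start <- integer(n_ex)
      seg_end <- integer(n_ex)
      at <- start
      off <- 0L
      for (j in seq_len(n_ex)) {
        seg_start[j] <- at
        seg_end[j] <- at + glens[j] - 1L
        inserts[[length(inserts) + 1L]] <-
          list(start = seg_start[j], end = seg_end[j],
               piece = substr(ins, off + 1L, off + glens[j]))
        off <- off + glens[j]
        if (j < n_ex) at <- seg_end[j] + introns[j] + 1L else at <- seg_end[j]
      }
      ph_tr <- c(0L, (3L - cumsum(parts) %% 3L) %% 3L)[seq_len(n_ex)]
      phases <- if (strand == "+") ph_tr else rev(ph_tr)
      gid <- sprintf("gene_%s_%02d", nms[ci], gi)
      genes[[gid]] <- gene_model(
        gene_id = gid, chrom = nms[ci], strand = strand,
        segments = data.frame(start = seg_start, end = seg_end),
        phases = phases
      )
      placed <- rbind(placed,
                      data.frame(start = start, end = start + span - 1L))
    }
    # splice all exon pieces into the background in one pass
    if (length(inserts) > 0L) {
      o <- order(vapply(inserts, `[[`, integer(1), "start"))
      inserts <- inserts[o]
      parts <- character(2L * length(inserts) + 1L)
      at <- 1L
      for (j in seq_along(inserts)) {
        iv <- inserts[[j]]
        parts[2L * j - 1L] <- substr(s, at, iv$start - 1L)
        parts[2L * j] <- iv$piece
        at <- iv$end + 1L
      }
      parts[2L * length(inserts) + 1L] <- substr(s, at, L)
      s <- paste(parts, collapse = "")
      stopifnot(nchar(s) == L)
    }
    seqs[ci] <- s
  }
  list(genome = Biostrings::DNAStringSet(stats::setNames(seqs, nms)),
       genes = unname(genes))
}

TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS_OF <- list(A = c("C", "T"), C = c("A", "G"),
                         G = c("C", "T"), T = c("A", "G"))

#' Induce a mutagenized line's SNP set
#'
#' Positions are sampled uniformly without replacement across the
#' genome; alternative alleles are transitions with probability
#' `transition_fraction` (the transition bias of alkylating mutagens
#' such as NMU), otherwise a random transversion.  Exactly one causal
#' mutation is forcibly placed at codon position 1 of a `CTC`/`CTT`
#' leucine codon inside a CDS, so the coding change is C->T and
#' Leu->Phe.  All mutations are homozygous in the mutant parent line.
#'
#' @param genome Genome.
#' @param genes List of [gene_model()] objects.
#' @param n_mutations Total number of induced SNPs (including the causal
#'   one).
#' @param transition_fraction Fraction of transitions among non-causal
#'   SNPs.
#' @param seed Integer seed.
#' @return A `mutation_set` data frame (`chrom`, `pos`, `ref`, `alt`,
#'   `is_causal`), sorted by position, with a `causal` attribute
#'   recording the targeted gene and residue.
#' @export
induce_mutations <- function(genome, genes, n_mutations = 300L,
                             transition_fraction = 0.9, seed = 1L) {
  set.seed(seed)
  stopifnot(n_mutations >= 1L,
            transition_fraction >= 0, transition_fraction <= 1)
  genome <- as_genome(genome)
  lens <- genome_lengths(genome)
  chrom_cache <- lapply(stats::setNames(nm = names(lens)),
                        function(cn) chrom_string(genome, cn))
  cds_from_cache <- function(g) {
    s <- chrom_cache[[g$chrom]]
    pieces <- substring(s, g$segments$start, g$segments$end)
    if (g$strand == "+") paste(pieces, collapse = "")
    else paste(revcomp(rev(pieces)), collapse = "")
  }
  # -- causal site: any CTC/CTT codon in any CDS -----------------------
  hits <- list()
  for (g in genes) {
    cod <- codons_of(cds_from_cache(g))
    idx <- which(cod %in% c("CTC", "CTT"))
    for (i in idx) hits[[length(hits) + 1L]] <- list(gene = g, codon = i)
  }
  if (length(hits) == 0L) {
    stop("no CTC/CTT leucine codon available in any CDS; ",
         "regenerate the reference (more or longer genes)")
  }
  pick <- hits[[sample.int(length(hits), 1L)]]
  cg <- pick$gene
  causal_offset <- (pick$codon - 1L) * 3L +
    cg$phases[if (cg$strand == "+") 1L else nrow(cg$segments)]
  causal_pos <- genomic_pos_of_offset(cg, causal_offset)
  causal_chrom <- cg$chrom
  causal_ref <- if (cg$strand == "+") "C" else "G"
  causal_alt <- if (cg$strand == "+") "T" else "A"
  stopifnot(substr(chrom_cache[[causal_chrom]],
                   causal_pos, causal_pos) == causal_ref)
  # -- background sites ------------------------------------------------
  total <- sum(lens)
  cum <- cumsum(as.numeric(lens))
  causal_global <- (if (causal_chrom == names(lens)[1L]) 0
                    else cum[match(causal_chrom, names(lens)) - 1L]) +
    causal_pos
  gpos <- integer(0)
  while (length(gpos) < n_mutations - 1L) {
    need <- n_mutations - 1L - length(gpos)
    extra <- sample.int(total, min(total, need + 20L))
    gpos <- unique(c(gpos, setdiff(extra, causal_global)))
  }
  gpos <- gpos[seq_len(n_mutations - 1L)]
  ch_i <- findInterval(gpos - 1, c(0, cum))  # chromosome index
  pos <- as.integer(gpos - c(0, cum)[ch_i])
  chrom <- names(lens)[ch_i]
  ref <- character(length(pos))
  for (cn in unique(chrom)) {
    sel <- chrom == cn
    ref[sel] <- substring(chrom_cache[[cn]], pos[sel], pos[sel])
  }
  is_trans <- runif(length(pos)) < transition_fraction
  alt <- ifelse(is_trans, TRANSITION_OF[ref],
                vapply(seq_along(ref), function(i) {
                  sample(TRANSVERSIONS_OF[[ref[i]]], 1L)
                }, character(1)))
  df <- data.frame(
    chrom = c(chrom, causal_chrom),
    pos = c(pos, causal_pos),
    ref = c(ref, causal_ref),
    alt = c(unname(alt), causal_alt),
    is_causal = c(rep(FALSE, length(pos)), TRUE),
    stringsAsFactors = FALSE
  )
  df <- df[order(match(df$chrom, names(lens)), df$pos), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            causal = list(chrom = causal_chrom, pos = causal_pos,
                          gene_id = cg$gene_id, aa_pos = pick$codon),
            class = c("mutation_set", "data.frame"))
}

# Truncated-normal draw on (0,1) by inverse-CDF; exact and vectorized.
rtrunc01 <- function(n, mean, sd) {
  lo <- pnorm(0, mean, sd)
  hi <- pnorm(1, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

#' Breed a BC1F2 population
#'
#' Each individual is formed from two independent F1 gametes.  Within a
#' gamete the parental haplotype switches at crossover points drawn as a
#' Poisson process with intensity `recomb_rate` crossovers per
#' chromosome (Haldane model, no interference).  The phenotype is
#' recessive at the causal site, flipped with probability
#' `misclassification`, and Fv/Fm is drawn from the phenotype-conditional
#' truncated normals of the design.
#'
#' Stream order: per chromosome (genome order) gamete start haplotypes,
#' then crossover counts, then crossover positions; then phenotype
#' flips; then Fv/Fm values.
#'
#' @param design A [cross_design()].
#' @param mutations A `mutation_set`.
#' @param chrom_lengths Named chromosome lengths (bp), or a genome.
#' @param seed Integer seed.
#' @return Object of class `bc1f2_population`: dosage matrix
#'   (individuals x sites, values 0/1/2 copies of the mutant-line
#'   allele), `phenotype`, `fvfm`, the mutation table and the causal
#'   column index.
#' @export
breed_bc1f2 <- function(design, mutations, chrom_lengths, seed = 1L) {
  set.seed(seed)
  if (!is.numeric(chrom_lengths)) {
    chrom_lengths <- genome_lengths(as_genome(chrom_lengths))
  }
  n <- design$n_population
  ng <- 2L * n
  m <- nrow(mutations)
  dosage <- matrix(0L, n, m)
  odd <- seq(1L, ng, 2L)
  even <- seq(2L, ng, 2L)
  for (ch in unique(mutations$chrom)) {
    idx <- which(mutations$chrom == ch)
    p <- mutations$pos[idx]
    L <- chrom_lengths[[ch]]
    start <- sample(c(0L, 1L), ng, replace = TRUE)
    k <- rpois(ng, design$recomb_rate)
    hap <- matrix(rep(start, length(idx)), ng, length(idx))
    tot <- sum(k)
    if (tot > 0L) {
      x <- runif(tot) * L
      g <- rep.int(seq_len(ng), k)
      for (j in seq_along(p)) {
        cnt <- tabulate(g[x < p[j]], nbins = ng)
        hap[, j] <- (start + cnt) %% 2L
      }
    }
    dosage[, idx] <- hap[odd, , drop = FALSE] + hap[even, , drop = FALSE]
  }
  ci <- which(mutations$is_causal)
  true_mut <- dosage[, ci] == 2L
  flip <- runif(n) < design$misclassification
  is_mut <- xor(true_mut, flip)
  phenotype <- ifelse(is_mut, "mutant", "wildtype-like")
  fvfm <- numeric(n)
  fvfm[is_mut] <- rtrunc01(sum(is_mut), design$fvfm_mut[["mean"]],
                           design$fvfm_mut[["sd"]])
  fvfm[!is_mut] <- rtrunc01(sum(!is_mut), design$fvfm_wt[["mean"]],
                            design$fvfm_wt[["sd"]])
  structure(
    list(dosage = dosage, phenotype = phenotype, fvfm = fvfm,
         mutations = mutations, causal_index = ci),
    class = "bc1f2_population"
  )
}

#' Select phenotype pools from a BC1F2 population
#'
#' The mutant pool takes the first `pool_sizes["mutant"]` individuals
#' labelled `mutant`, the azygous pool the first
#' `pool_sizes["azygous"]` labelled `wildtype-like`.  The wild-type pool
#' is the un-mutagenized parent: it carries zero mutant-line alleles at
#' every induced site.
#'
#' @param population A `bc1f2_population`.
#' @param design A [cross_design()].
#' @return Object of class `pool_set`: matrix `fractions` (pool x site
#'   mutant-allele dosage fraction), pool membership and sizes.
#' @export
make_pools <- function(population, design) {
  ps <- design$pool_sizes
  mut_idx <- which(population$phenotype == "mutant")
  az_idx <- which(population$phenotype == "wildtype-like")
  if (length(mut_idx) < ps[["mutant"]] || length(az_idx) < ps[["azygous"]]) {
    stop("insufficient individuals per phenotype class (",
         length(mut_idx), " mutant, ", length(az_idx),
         " wildtype-like); increase n_population")
  }
  mut_idx <- mut_idx[seq_len(ps[["mutant"]])]
  az_idx <- az_idx[seq_len(ps[["azygous"]])]
  d <- population$dosage
  fractions <- rbind(
    mutant = colSums(d[mut_idx, , drop = FALSE]) / (2 * ps[["mutant"]]),
    azygous = colSums(d[az_idx, , drop = FALSE]) / (2 * ps[["azygous"]]),
    wildtype = 0
  )
  structure(
    list(fractions = fractions,
         members = list(mutant = mut_idx, azygous = az_idx),
         sizes = ps, mutations = population$mutations,
         causal_index = population$causal_index),
    class = "pool_set"
  )
}

# Pooled-call GT/GQ: likelihoods of the three diploid-pool hypotheses
# (alt fraction ~0, 0.5, ~1, shifted by the per-read error rate);
# GT is the argmax call, GQ the Phred-scaled ratio of the two best
# likelihoods, capped at 99.  A monotone Phred-scale confidence in the
# call, matching the behavior the downstream GQ >= 30 threshold assumes
# (homozygous calls earn roughly 3 Phred per supporting read).
genotype_call <- function(ad_alt, dp, seq_error) {
  fg <- c(seq_error, 0.5, 1 - seq_error)
  calls <- c("0/0", "0/1", "1/1")
  ll <- vapply(fg, function(f) dbinom(ad_alt, dp, f, log = TRUE),
               numeric(length(ad_alt)))
  ll <- matrix(ll, ncol = 3L)
  best <- max.col(ll, ties.method = "first")
  l1 <- ll[cbind(seq_along(ad_alt), best)]
  l2 <- apply(ll, 1L, function(r) sort(r, decreasing = TRUE)[2L])
  gq <- as.integer(pmin(99, round(10 * (l1 - l2) / log(10))))
  gt <- calls[best]
  gt[dp == 0L] <- "./."
  gq[dp == 0L] <- 0L
  list(gt = gt, gq = gq)
}

#' Simulate pooled sequencing reads at every induced site
#'
#' Per site and pool, depth is Poisson with a mean drawn uniformly from
#' the design's coverage range; alt-read counts are binomial with
#' success probability equal to the pool's mutant-allele dosage
#' fraction perturbed by the per-read error rate (error reads flip
#' allele).  GT/GQ come from the three-hypothesis pooled-call model
#' (see the methods vignette).
#'
#' Stream order: pools in the fixed order mutant, azygous, wildtype;
#' within a pool: depth means, depths, alt counts.
#'
#' @param pools A `pool_set`.
#' @param design A [cross_design()].
#' @param seed Integer seed.
#' @return A `pool_variants` data frame (one row per induced site).
#' @export
simulate_pool_reads <- function(pools, design, seed = 1L) {
  set.seed(seed)
  mut <- pools$mutations
  m <- nrow(mut)
  e <- design$seq_error
  cov <- design$coverage_range
  samples <- list()
  for (p in c("mutant", "azygous", "wildtype")) {
    f <- pools$fractions[p, ]
    lambda <- runif(m, cov[1], cov[2])
    dp <- rpois(m, lambda)
    pe <- f * (1 - e) + (1 - f) * e
    ad_alt <- rbinom(m, dp, pe)
    gl <- genotype_call(ad_alt, dp, e)
    samples[[p]] <- data.frame(ad_ref = dp - ad_alt, ad_alt = ad_alt,
                               dp = dp, gq = gl$gq, gt = gl$gt,
                               stringsAsFactors = FALSE)
  }
  out <- pool_variants(chrom = mut$chrom, pos = mut$pos, ref = mut$ref,
                       alt = mut$alt, samples = samples)
  attr(out, "is_causal") <- mut$is_causal
  out
}
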