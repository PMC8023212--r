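# In-code fixtures: compact builders for pooled variant tables and tiny
# hand-laid genomes used across the test files.

# Strip non-structural attributes so variant tables can be compared on
# content alone.
plain <- function(x) {
  x <- as.data.frame(x)
  attributes(x) <- attributes(x)[c("names", "class", "row.names")]
  x
}

# Build a pool_variants table from allele-frequency specs.  AFs are
# converted to integer alt counts at the given depth; NA means no
# usable reads (depth 0).
mk_records <- function(af_mut, dp_mut = 50L, gq_mut = 99L,
                       af_az = 0.33, dp_az = 50L,
                       af_wt = 0, dp_wt = 50L,
                       chrom = "chr1", pos = NULL) {
  n <- length(af_mut)
  dp_mut <- rep_len(dp_mut, n); gq_mut <- rep_len(gq_mut, n)
  af_az <- rep_len(af_az, n); dp_az <- rep_len(dp_az, n)
  af_wt <- rep_len(af_wt, n); dp_wt <- rep_len(dp_wt, n)
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  smp <- function(af, dp) {
    dp <- ifelse(is.na(af), 0L, dp)
    aa <- ifelse(is.na(af), 0L, as.integer(round(af * dp)))
    data.frame(ad_ref = dp - aa, ad_alt = aa, dp = dp,
               gq = rep_len(99L, n), gt = rep_len("0/1", n))
  }
  s_m <- smp(af_mut, dp_mut); s_m$gq <- gq_mut
  pool_variants(chrom = rep_len(chrom, n), pos = pos,
                ref = rep_len("C", n), alt = rep_len("T", n),
                samples = list(mutant = s_m,
                               azygous = smp(af_az, dp_az),
                               wildtype = smp(af_wt, dp_wt)))
}

# A 60 bp chromosome with a single-exon plus-strand gene whose CDS is
# ATG CTC TGA at positions 21..29.
toy_plus_gene <- function() {
  filler <- strrep("A", 20)
  s <- paste0(filler, "ATGCTCTGA", strrep("G", 31))
  genome <- Biostrings::DNAStringSet(c(chr1 = s))
  gene <- gene_model("g1", "chr1", "+",
                     data.frame(start = 21L, end = 29L), phases = 0L)
  list(genome = genome, gene = gene)
}

# Same CDS carried on the minus strand: genomic sequence holds the
# reverse complement of ATGCTCTGA (= TCAGAGCAT) at positions 21..29.
toy_minus_gene <- function() {
  filler <- strrep("A", 20)
  s <- paste0(filler, "TCAGAGCAT", strrep("G", 31))
  genome <- Biostrings::DNAStringSet(c(chr1 = s))
  gene <- gene_model("g1", "chr1", "-",
                     data.frame(start = 21L, end = 29L), phases = 0L)
  list(genome = genome, gene = gene)
}

# Exhaustive enumeration oracle for the selfed-F1 pooled allele
# frequency: the 16 ordered F1 gamete pairs at two linked loci (causal
# M/m, marker A/a in coupling), in exact integer arithmetic for
# r = k/20.  Gamete probability numerators over denominator 40:
# MA and ma get 20 - k, Ma and mA get k.
enumerate_pool_af <- function(k, pool) {
  gam <- list(c(M = 1L, A = 1L), c(M = 1L, A = 0L),
              c(M = 0L, A = 1L), c(M = 0L, A = 0L))
  wnum <- c(20L - k, k, k, 20L - k)
  num <- 0L   # sum of weights * marker-allele count
  den <- 0L   # sum of weights (x2 alleles)
  for (i in 1:4) {
    for (j in 1:4) {
      w <- wnum[i] * wnum[j]
      mm <- gam[[i]]["M"] + gam[[j]]["M"]
      sel <- switch(pool,
                    mutant = mm == 2L,
                    azygous = mm < 2L)
      if (sel) {
        num <- num + w * (gam[[i]]["A"] + gam[[j]]["A"])
        den <- den + 2L * w
      }
    }
  }
  unname(num / den)
}

# Brute-force coding-effect oracle: rebuild the mutant chromosome,
# re-extract the spliced CDS with Biostrings, translate both alleles
# and diff the proteins.  Fully independent of annotate_effect()'s
# codon arithmetic.
oracle_effect <- function(chrom_seq, pos, alt, gene) {
  mut_seq <- chrom_seq
  substr(mut_seq, pos, pos) <- alt
  splice <- function(s) {
    pieces <- Biostrings::DNAStringSet(
      substring(s, gene$segments$start, gene$segments$end))
    cds <- Biostrings::DNAString(paste(as.character(pieces), collapse = ""))
    if (gene$strand == "-") cds <- Biostrings::reverseComplement(cds)
    as.character(Biostrings::translate(cds, no.init.codon = TRUE))
  }
  p_ref <- splice(chrom_seq)
  p_alt <- splice(mut_seq)
  d <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])
  if (length(d) == 0L) {
    return(list(effect_class = "synonymous", aa_pos = NA_integer_))
  }
  i <- d[1L]
  aa_r <- substr(p_ref, i, i)
  aa_a <- substr(p_alt, i, i)
  cls <- if (aa_a == "*") {
    "nonsense"
  } else if (aa_r == "*") {
    "stop_loss"
  } else if (i == 1L && aa_r == "M") {
    "start_loss"
  } else {
    "missense"
  }
  list(effect_class = cls, aa_pos = i, aa_ref = aa_r, aa_alt = aa_a)
}
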