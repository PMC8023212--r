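# Pooled variant tables and VCF 4.2 input/output.  The in-memory
# container ("pool_variants") is a data frame with one row per bi-allelic
# SNP and, for every pool, the read-count evidence columns
# <pool>.ad_ref, <pool>.ad_alt, <pool>.dp, <pool>.gq, <pool>.gt.
# Reading goes through vcfR; writing is a minimal plain-text VCFv4.2
# emitter (FORMAT GT:AD:DP:GQ, FILTER unused -- filtering decisions live
# in the candidate report, not in the record).

#' Assemble a pooled variant table
#'
#' @param chrom,pos,ref,alt Per-site columns; `pos` is 1-based; `ref`
#'   and `alt` are single distinct bases.
#' @param samples Named list (one element per pool) of data frames with
#'   columns `ad_ref`, `ad_alt`, `dp`, `gq`, `gt`.
#' @return A `pool_variants` data frame with attribute `pools`.
#' @export
pool_variants <- function(chrom, pos, ref, alt, samples) {
  stopifnot(length(samples) >= 1L, !is.null(names(samples)))
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   stringsAsFactors = FALSE)
  if (any(df$ref == df$alt)) stop("ref and alt must differ")
  for (p in names(samples)) {
    s <- samples[[p]]
    if (any(s$ad_ref + s$ad_alt > s$dp)) {
      stop("pool '", p, "': ad_ref + ad_alt exceeds dp")
    }
    if (any(s$gq < 0)) stop("pool '", p, "': negative GQ")
    for (f in c("ad_ref", "ad_alt", "dp", "gq", "gt")) {
      df[[paste0(p, ".", f)]] <- s[[f]]
    }
  }
  structure(df, pools = names(samples),
            class = c("pool_variants", "data.frame"))
}

variant_pools <- function(records) {
  p <- attr(records, "pools")
  if (is.null(p)) stop("not a pool_variants table (missing 'pools' attribute)")
  p
}

# Per-pool field accessor with an explicit unknown-pool error.
pool_field <- function(records, pool, field) {
  if (!pool %in% variant_pools(records)) {
    stop("unknown pool '", pool, "'; pools are: ",
         paste(variant_pools(records), collapse = ", "))
  }
  records[[paste0(pool, ".", field)]]
}

# Subset rows while preserving the pool_variants attributes.
subset_variants <- function(records, keep) {
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pools") <- attr(records, "pools")
  class(out) <- c("pool_variants", "data.frame")
  out
}

#' Read pooled variant calls from a VCF file
#'
#' Retains bi-allelic SNP rows whose FORMAT carries `GT`, `AD`, `DP` and
#' `GQ`; multi-allelic and indel rows are skipped and counted in the
#' `n_skipped` attribute (also reported via [message()]).
#'
#' @param path Plain-text VCF v4.2 with one sample column per pool.
#' @return A `pool_variants` data frame.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt <- v@gt
  pools <- colnames(gt)[-1L]
  fmt_keys <- strsplit(gt[, "FORMAT"], ":", fixed = TRUE)
  need <- c("GT", "AD", "DP", "GQ")
  ok_fmt <- vapply(fmt_keys, function(k) all(need %in% k), logical(1))
  if (any(!ok_fmt)) {
    i <- which(!ok_fmt)[1L]
    miss <- setdiff(need, fmt_keys[[i]])
    stop("VCF parse error at record ", fix[i, "CHROM"], ":", fix[i, "POS"],
         ": FORMAT lacks key(s) ", paste(miss, collapse = ","))
  }
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!snp)
  if (n_skipped > 0L) {
    message("read_vcf: skipped ", n_skipped,
            " multi-allelic/indel record(s)")
  }
  get_el <- function(el) vcfR::extract.gt(v, element = el)[snp, , drop = FALSE]
  gt_m <- get_el("GT")
  ad_m <- get_el("AD")
  dp_m <- get_el("DP")
  gq_m <- get_el("GQ")
  samples <- list()
  for (j in seq_along(pools)) {
    ad <- strsplit(ad_m[, j], ",", fixed = TRUE)
    samples[[pools[j]]] <- data.frame(
      ad_ref = vapply(ad, function(x) as.integer(x[1L]), integer(1)),
      ad_alt = vapply(ad, function(x) as.integer(x[2L]), integer(1)),
      dp = as.integer(dp_m[, j]),
      gq = as.integer(gq_m[, j]),
      gt = unname(gt_m[, j]),
      stringsAsFactors = FALSE
    )
  }
  out <- pool_variants(chrom = fix[snp, "CHROM"],
                       pos = as.integer(fix[snp, "POS"]),
                       ref = ref[snp], alt = alt[snp], samples = samples)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write pooled variant calls to a plain-text VCF 4.2 file
#'
#' Emits a minimal header (contig lines when a genome is supplied, the
#' four FORMAT declarations) and one sample column per pool with
#' `GT:AD:DP:GQ` fields.  Round-trips through [read_vcf()] bit-exactly
#' on the retained fields.
#'
#' @param records A `pool_variants` data frame.
#' @param path Output path.
#' @param genome Optional genome used to emit `##contig` lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, genome = NULL) {
  pools <- variant_pools(records)
  hdr <- "##fileformat=VCFv4.2"
  if (!is.null(genome)) {
    lens <- genome_lengths(as_genome(genome))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(lens), lens))
  }
  hdr <- c(
    hdr,
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Pooled genotype call">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Phred-scaled call quality">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", pools), collapse = "\t")
  )
  cols <- lapply(pools, function(p) {
    sprintf("%s:%d,%d:%d:%d",
            pool_field(records, p, "gt"),
            pool_field(records, p, "ad_ref"),
            pool_field(records, p, "ad_alt"),
            pool_field(records, p, "dp"),
            pool_field(records, p, "gq"))
  })
  body <- if (nrow(records) == 0L) {
    character(0)
  } else {
    do.call(paste, c(
      list(records$chrom, records$pos, ".", records$ref, records$alt,
           ".", ".", ".", "GT:AD:DP:GQ"),
      cols, sep = "\t"
    ))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
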