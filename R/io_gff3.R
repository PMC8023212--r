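# Gene models and GFF3 input/output.  A gene model is the spliced CDS
# of one mRNA: ordered genomic segments plus per-segment phase.  All
# on-disk coordinates are 1-based inclusive (GFF3 convention); interval
# arithmetic inside the package is 0-based half-open via the converters
# in seq_utils.R.

#' Construct a gene model
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param segments Data frame with `start`, `end` (1-based inclusive
#'   genomic coordinates), sorted and non-overlapping.
#' @param phases Integer vector in `0:2`, one per segment (genomic
#'   order), GFF3 phase semantics: bases to skip at the translational
#'   start of the segment to reach the first complete codon.
#' @param transcript_id Optional transcript identifier (defaults to
#'   `<gene_id>.1`).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, segments, phases,
                       transcript_id = paste0(gene_id, ".1")) {
  segments <- as.data.frame(segments)[, c("start", "end")]
  segments$start <- as.integer(segments$start)
  segments$end <- as.integer(segments$end)
  phases <- as.integer(phases)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (nrow(segments) == 0L) stop("gene model needs at least one CDS segment")
  if (any(segments$end < segments$start)) stop("segment end < start")
  if (length(phases) != nrow(segments)) {
    stop("need one phase per CDS segment")
  }
  if (any(!phases %in% 0:2)) stop("phases must be in 0:2")
  o <- order(segments$start)
  segments <- segments[o, , drop = FALSE]
  phases <- phases[o]
  if (nrow(segments) > 1L &&
      any(segments$start[-1L] <= segments$end[-nrow(segments)])) {
    stop("CDS segments overlap in gene '", gene_id, "'")
  }
  lens <- segments$end - segments$start + 1L
  first_tr <- if (strand == "+") 1L else nrow(segments)
  if ((sum(lens) - phases[first_tr]) %% 3L != 0L) {
    stop("CDS length of gene '", gene_id,
         "' not divisible by 3 after phase adjustment")
  }
  structure(
    list(gene_id = gene_id, transcript_id = transcript_id, chrom = chrom,
         strand = strand, segments = segments, phases = phases),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) %s:%d-%d, %d CDS segment(s), %d bp\n",
              x$gene_id, x$strand, x$chrom, min(x$segments$start),
              max(x$segments$end), nrow(x$segments), cds_length(x)))
  invisible(x)
}

cds_length <- function(gene) {
  sum(gene$segments$end - gene$segments$start + 1L)
}

gene_span <- function(gene) {
  c(start = min(gene$segments$start), end = max(gene$segments$end))
}

#' Spliced CDS of a gene model, in translation orientation
#'
#' @param gene A [gene_model()].
#' @param genome Genome ([Biostrings::DNAStringSet] or named character).
#' @return Character scalar (minus-strand models are reverse-complemented
#'   segment-by-segment into 5'->3' coding order).
#' @export
spliced_cds <- function(gene, genome) {
  s <- chrom_string(as_genome(genome), gene$chrom)
  pieces <- substring(s, gene$segments$start, gene$segments$end)
  if (gene$strand == "+") {
    paste(pieces, collapse = "")
  } else {
    paste(revcomp(rev(pieces)), collapse = "")
  }
}

# 0-based offset within the spliced CDS (translation orientation) of a
# genomic position, or NA if the position is not inside a CDS segment.
cds_offset_of <- function(gene, pos) {
  seg <- gene$segments
  lens <- seg$end - seg$start + 1L
  j <- which(pos >= seg$start & pos <= seg$end)
  if (length(j) == 0L) return(NA_integer_)
  j <- j[1L]
  if (gene$strand == "+") {
    sum(lens[seq_len(j - 1L)]) + (pos - seg$start[j])
  } else {
    k <- nrow(seg)
    extra <- if (j < k) sum(lens[(j + 1L):k]) else 0L
    extra + (seg$end[j] - pos)
  }
}

# Inverse of cds_offset_of(): genomic position of a CDS offset.
genomic_pos_of_offset <- function(gene, offset) {
  seg <- gene$segments
  lens <- seg$end - seg$start + 1L
  ord <- if (gene$strand == "+") seq_len(nrow(seg)) else rev(seq_len(nrow(seg)))
  cum <- 0L
  for (j in ord) {
    if (offset < cum + lens[j]) {
      within <- offset - cum
      return(if (gene$strand == "+") seg$start[j] + within
             else seg$end[j] - within)
    }
    cum <- cum + lens[j]
  }
  stop("CDS offset ", offset, " out of range for gene '", gene$gene_id, "'")
}

#' Read gene models from a GFF3 file
#'
#' CDS rows are grouped by parent mRNA; models violating the gene-model
#' invariants (for example a spliced length not divisible by 3 after
#' phase adjustment) are skipped with a warning.  Minus-strand models
#' keep genomic coordinates and are marked by `strand`.
#'
#' @param path Path to a plain-text GFF3 file with gene/mRNA/CDS rows.
#' @param keep Which transcript to retain per gene: `"first"` (default,
#'   file order), `"longest"` (by spliced CDS length), or `"all"`.
#' @return List of [gene_model()] objects.
#' @export
read_gff3 <- function(path, keep = c("first", "longest", "all")) {
  keep <- match.arg(keep)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- as.data.frame(rtracklayer::readGFF(path))
  cds <- df[df$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) return(list())
  parent1 <- vapply(cds$Parent, function(p) {
    if (length(p) == 0L) NA_character_ else p[[1L]]
  }, character(1))
  if (anyNA(parent1)) {
    i <- which(is.na(parent1))[1L]
    stop("GFF3 format error: CDS at ", cds$seqid[i], ":", cds$start[i],
         " has no Parent")
  }
  if (anyNA(cds$phase)) {
    i <- which(is.na(cds$phase))[1L]
    stop("GFF3 format error: CDS at ", cds$seqid[i], ":", cds$start[i],
         " has phase '.'")
  }
  mrna <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  mrna_gene <- stats::setNames(
    vapply(mrna$Parent, function(p) {
      if (length(p) == 0L) NA_character_ else p[[1L]]
    }, character(1)),
    mrna$ID
  )
  tx_ids <- unique(parent1)
  models <- list()
  for (tx in tx_ids) {
    rows <- cds[parent1 == tx, , drop = FALSE]
    gid <- if (tx %in% names(mrna_gene) && !is.na(mrna_gene[[tx]])) {
      mrna_gene[[tx]]
    } else {
      tx  # CDS attached directly to a gene feature
    }
    gm <- tryCatch(
      gene_model(gene_id = gid, transcript_id = tx,
                 chrom = as.character(rows$seqid[1L]),
                 strand = as.character(rows$strand[1L]),
                 segments = data.frame(start = rows$start, end = rows$end),
                 phases = rows$phase),
      error = function(e) {
        warning("skipping transcript '", tx, "': ", conditionMessage(e),
                call. = FALSE)
        NULL
      }
    )
    if (!is.null(gm)) models[[tx]] <- gm
  }
  if (keep == "all" || length(models) == 0L) return(unname(models))
  by_gene <- split(models, vapply(models, `[[`, character(1), "gene_id"))
  picked <- lapply(by_gene, function(ms) {
    if (keep == "first") {
      ms[[1L]]
    } else {
      ms[[which.max(vapply(ms, cds_length, integer(1)))]]
    }
  })
  unname(picked[order(vapply(picked, function(g) g$gene_id, character(1)))])
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA and CDS rows with `ID`/`Parent` attributes and
#' per-segment phase, 1-based inclusive coordinates.
#'
#' @param genes List of [gene_model()] objects.
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path, source = "bsamap") {
  lines <- "##gff-version 3"
  for (g in genes) {
    span <- gene_span(g)
    lines <- c(
      lines,
      paste(g$chrom, source, "gene", span["start"], span["end"], ".",
            g$strand, ".", paste0("ID=", g$gene_id), sep = "\t"),
      paste(g$chrom, source, "mRNA", span["start"], span["end"], ".",
            g$strand, ".",
            paste0("ID=", g$transcript_id, ";Parent=", g$gene_id), sep = "\t")
    )
    for (i in seq_len(nrow(g$segments))) {
      lines <- c(
        lines,
        paste(g$chrom, source, "CDS", g$segments$start[i], g$segments$end[i],
              ".", g$strand, g$phases[i],
              paste0("ID=", g$transcript_id, ".cds;Parent=", g$transcript_id),
              sep = "\t")
      )
    }
  }
  writeLines(lines, path)
  invisible(path)
}
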