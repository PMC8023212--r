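# Coding-effect annotation: place a variant in genomic context
# (intergenic / intronic / CDS) and compute its strand- and phase-aware
# codon and amino-acid consequence under the standard genetic code.

EFFECT_SEVERITY <- c(nonsense = 1, start_loss = 1, missense = 2,
                     synonymous = 3, intronic = 4, intergenic = 5)

#' Locate a variant relative to gene models
#'
#' @param chrom,pos Variant coordinates (1-based).
#' @param genes List of [gene_model()] objects.
#' @return List of contexts, one per overlapping gene: each a list with
#'   `type` (`"cds"` or `"intronic"`), `gene_id`, and for CDS contexts
#'   `cds_offset` (0-based offset in the spliced CDS, translation
#'   orientation).  An empty list means intergenic.
#' @export
locate_variant <- function(chrom, pos, genes) {
  out <- list()
  for (g in genes) {
    if (g$chrom != chrom) next
    span <- gene_span(g)
    if (pos < span["start"] || pos > span["end"]) next
    off <- cds_offset_of(g, pos)
    out[[length(out) + 1L]] <- if (is.na(off)) {
      list(type = "intronic", gene_id = g$gene_id)
    } else {
      list(type = "cds", gene_id = g$gene_id, cds_offset = off)
    }
  }
  out
}

#' Annotate the coding effect of a variant inside a CDS
#'
#' The codon index is `cds_offset %/% 3` (after removing the initial
#' phase), the within-codon index `cds_offset %% 3`; the alternative
#' base is complemented for minus-strand genes before substitution.
#' Effect classes: `synonymous`, `missense`, `nonsense` (alt codon is a
#' stop), `stop_loss` (ref codon is a stop, alt is not), `start_loss`
#' (codon 1 loses Met).
#'
#' @param chrom,pos,ref,alt Variant (genomic strand, single bases).
#' @param gene The [gene_model()] whose CDS contains the variant.
#' @param genome Genome; the reference base at `pos` must equal `ref`
#'   (a mismatch signals a coordinate bug and raises an error).
#' @return One-row data frame: `gene`, `effect_class`, `codon_ref`,
#'   `codon_alt`, `codon_change`, `aa_ref`, `aa_alt`, `aa_pos`,
#'   `aa_change`.
#' @export
annotate_effect <- function(chrom, pos, ref, alt, gene, genome) {
  genome <- as_genome(genome)
  gbase <- substr(chrom_string(genome, chrom), pos, pos)
  if (gbase != ref) {
    stop("reference mismatch at ", chrom, ":", pos, ": genome has '",
         gbase, "', variant says '", ref, "'")
  }
  off <- cds_offset_of(gene, pos)
  if (is.na(off)) stop("position ", pos, " is not inside the CDS of '",
                       gene$gene_id, "'")
  first_tr <- if (gene$strand == "+") 1L else nrow(gene$segments)
  phase0 <- gene$phases[first_tr]
  off2 <- off - phase0
  if (off2 < 0L) {
    stop("position ", pos, " lies upstream of the first complete codon of '",
         gene$gene_id, "'")
  }
  cds <- spliced_cds(gene, genome)
  ci <- off2 %/% 3L
  wi <- off2 %% 3L
  codon_ref <- substr(cds, phase0 + ci * 3L + 1L, phase0 + ci * 3L + 3L)
  alt_cds <- if (gene$strand == "+") alt else comp_base(alt)
  codon_alt <- codon_ref
  substr(codon_alt, wi + 1L, wi + 1L) <- alt_cds
  aa_ref <- unname(CODON_TABLE[codon_ref])
  aa_alt <- unname(CODON_TABLE[codon_alt])
  effect <- if (aa_ref == aa_alt) {
    "synonymous"
  } else if (aa_alt == "*") {
    "nonsense"
  } else if (aa_ref == "*") {
    "stop_loss"
  } else if (ci == 0L && aa_ref == "M") {
    "start_loss"
  } else {
    "missense"
  }
  aa_pos <- ci + 1L
  data.frame(gene = gene$gene_id, effect_class = effect,
             codon_ref = codon_ref, codon_alt = codon_alt,
             codon_change = paste0(codon_ref, ">", codon_alt),
             aa_ref = aa_ref, aa_alt = aa_alt, aa_pos = aa_pos,
             aa_change = paste0(aa_ref, aa_pos, aa_alt),
             stringsAsFactors = FALSE)
}

# Annotate one variant against all its contexts and keep the most
# severe consequence (all-context rows available via keep_all).
annotate_one <- function(chrom, pos, ref, alt, genes, genome,
                         keep_all = FALSE) {
  ctx <- locate_variant(chrom, pos, genes)
  base <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                     stringsAsFactors = FALSE)
  if (length(ctx) == 0L) {
    rows <- data.frame(base, gene = NA_character_,
                       effect_class = "intergenic",
                       codon_ref = NA_character_, codon_alt = NA_character_,
                       codon_change = NA_character_, aa_ref = NA_character_,
                       aa_alt = NA_character_, aa_pos = NA_integer_,
                       aa_change = NA_character_, stringsAsFactors = FALSE)
  } else {
    rows <- do.call(rbind, lapply(ctx, function(cx) {
      if (cx$type == "intronic") {
        data.frame(base, gene = cx$gene_id, effect_class = "intronic",
                   codon_ref = NA_character_, codon_alt = NA_character_,
                   codon_change = NA_character_, aa_ref = NA_character_,
                   aa_alt = NA_character_, aa_pos = NA_integer_,
                   aa_change = NA_character_, stringsAsFactors = FALSE)
      } else {
        g <- genes[[which(vapply(genes, `[[`, character(1), "gene_id") ==
                            cx$gene_id)[1L]]]
        cbind(base, annotate_effect(chrom, pos, ref, alt, g, genome))
      }
    }))
  }
  if (keep_all) return(rows)
  rows[order(EFFECT_SEVERITY[rows$effect_class])[1L], , drop = FALSE]
}

#' Annotate and prioritize candidate variants
#'
#' Each candidate gets its most severe consequence across overlapping
#' gene models; the output is sorted by severity
#' (nonsense/start_loss > missense > synonymous > intronic >
#' intergenic), ties broken by descending `linkage_score` (when
#' present), then by position.
#'
#' @param candidates `pool_variants` (optionally with `linkage_score`).
#' @param genes List of [gene_model()] objects.
#' @param genome Genome.
#' @return Data frame of annotations, one row per candidate, ranked.
#' @export
annotate_candidates <- function(candidates, genes, genome) {
  if (nrow(candidates) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gene = character(0), effect_class = character(0),
                      codon_ref = character(0), codon_alt = character(0),
                      codon_change = character(0), aa_ref = character(0),
                      aa_alt = character(0), aa_pos = integer(0),
                      aa_change = character(0), linkage_score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  genome <- as_genome(genome)
  ann <- do.call(rbind, lapply(seq_len(nrow(candidates)), function(i) {
    annotate_one(candidates$chrom[i], candidates$pos[i],
                 candidates$ref[i], candidates$alt[i], genes, genome)
  }))
  ann$linkage_score <- if ("linkage_score" %in% names(candidates)) {
    candidates$linkage_score
  } else {
    NA_real_
  }
  sev <- EFFECT_SEVERITY[ann$effect_class]
  ls <- ifelse(is.na(ann$linkage_score), -Inf, ann$linkage_score)
  o <- order(sev, -ls, ann$chrom, ann$pos)
  out <- ann[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}
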