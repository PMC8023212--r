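# Per-pool allele frequencies and the candidate-variant filters: the
# mutant-pool artifact/depth/quality screen, the mutant-vs-azygous
# association rule (AF = 1 in the mutant pool, < 0.5 in the azygous
# pool, absent from the wild-type pool), and a local linkage-
# consistency score.

#' Filtering thresholds for pooled variant calls
#'
#' Defaults mirror the published mapping filters: variants with a
#' mutant-pool allele frequency <= 0.3 are treated as alignment
#' artifacts; at least 10 supporting reads and GQ >= 30 are required in
#' the mutant pool; candidates need AF >= 1.0 (minus `mutant_af_tolerance`)
#' in the mutant pool, AF < 0.5 in the azygous pool, and (by default)
#' absence from the wild-type pool.
#'
#' @param min_depth Minimum mutant-pool depth (`ad_ref + ad_alt`).
#' @param min_gq_mutant Minimum mutant-pool GQ (Phred).
#' @param artifact_af_max Mutant-pool AF at or below which a variant is
#'   discarded as an alignment artifact (inclusive threshold).
#' @param mutant_af_min Required mutant-pool AF (default exactly 1.0).
#' @param mutant_af_tolerance Slack subtracted from `mutant_af_min`;
#'   finite coverage plus sequencing error makes exact 1.0 fragile.
#' @param azygous_af_max Strict upper bound on the azygous-pool AF.
#' @param require_absent_in_wildtype Apply the wild-type exclusion rule.
#' @param wildtype_af_max Maximum wild-type-pool AF when required.
#' @param azygous_missing `"drop"` (default) or `"keep"`: policy for
#'   records whose azygous-pool AF is undefined (zero used reads).
#' @param gq_scope `"mutant"` (default) applies the GQ rule to the
#'   mutant pool only; `"all"` applies it to every pool.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_depth = 10L, min_gq_mutant = 30L,
                          artifact_af_max = 0.3,
                          mutant_af_min = 1.0, mutant_af_tolerance = 0,
                          azygous_af_max = 0.5,
                          require_absent_in_wildtype = TRUE,
                          wildtype_af_max = 0,
                          azygous_missing = c("drop", "keep"),
                          gq_scope = c("mutant", "all")) {
  azygous_missing <- match.arg(azygous_missing)
  gq_scope <- match.arg(gq_scope)
  fracs <- c(artifact_af_max, mutant_af_min, mutant_af_tolerance,
             azygous_af_max, wildtype_af_max)
  stopifnot(min_depth >= 1L, min_gq_mutant >= 0,
            all(fracs >= 0), all(fracs <= 1))
  structure(
    list(min_depth = as.integer(min_depth),
         min_gq_mutant = as.integer(min_gq_mutant),
         artifact_af_max = artifact_af_max,
         mutant_af_min = mutant_af_min,
         mutant_af_tolerance = mutant_af_tolerance,
         azygous_af_max = azygous_af_max,
         require_absent_in_wildtype = require_absent_in_wildtype,
         wildtype_af_max = wildtype_af_max,
         azygous_missing = azygous_missing,
         gq_scope = gq_scope),
    class = "filter_config"
  )
}

#' Per-pool allele frequency of each variant
#'
#' AF is `ad_alt / (ad_ref + ad_alt)` and is `NA` (flagged missing)
#' when no used reads cover the site.
#'
#' @param records A `pool_variants` data frame.
#' @param pool Pool name present in the records.
#' @return Data frame `chrom`, `pos`, `pool`, `af`, `depth_used`, `gq`.
#' @export
compute_af <- function(records, pool) {
  ar <- pool_field(records, pool, "ad_ref")
  aa <- pool_field(records, pool, "ad_alt")
  du <- ar + aa
  data.frame(chrom = records$chrom, pos = records$pos,
             pool = rep_len(pool, nrow(records)),
             af = ifelse(du > 0L, aa / du, NA_real_),
             depth_used = du, gq = pool_field(records, pool, "gq"),
             stringsAsFactors = FALSE)
}

#' Apply the mutant-pool quality filters
#'
#' A record is dropped iff its mutant-pool AF is at or below the
#' artifact threshold, its mutant-pool used depth is below `min_depth`,
#' or its mutant-pool GQ is below `min_gq_mutant` (optionally every
#' pool's GQ with `gq_scope = "all"`).  Drop counts attribute each
#' dropped record to the first matching rule in the fixed order
#' af, depth, gq.
#'
#' @param records A `pool_variants` data frame carrying a `mutant` pool.
#' @param config A [filter_config()].
#' @return `list(retained, drop_counts, n_input)`.
#' @export
apply_quality_filters <- function(records, config = filter_config()) {
  af <- compute_af(records, "mutant")
  r_af <- !is.na(af$af) & af$af <= config$artifact_af_max
  r_dp <- af$depth_used < config$min_depth
  r_gq <- af$gq < config$min_gq_mutant
  if (config$gq_scope == "all") {
    for (p in setdiff(variant_pools(records), "mutant")) {
      r_gq <- r_gq | pool_field(records, p, "gq") < config$min_gq_mutant
    }
  }
  dropped <- r_af | r_dp | r_gq
  first <- rep(NA_character_, nrow(records))
  first[r_gq] <- "gq"
  first[r_dp] <- "depth"
  first[r_af] <- "af"
  drop_counts <- c(af = sum(first == "af", na.rm = TRUE),
                   depth = sum(first == "depth", na.rm = TRUE),
                   gq = sum(first == "gq", na.rm = TRUE))
  list(retained = subset_variants(records, !dropped),
       drop_counts = drop_counts, n_input = nrow(records))
}

#' Select candidate causal variants
#'
#' Keeps records whose mutant-pool AF reaches `mutant_af_min` (within
#' tolerance), whose azygous-pool AF is strictly below
#' `azygous_af_max`, and which are absent from the wild-type pool when
#' required.  Intended to run on the output of
#' [apply_quality_filters()].
#'
#' @param records Quality-filtered `pool_variants`.
#' @param config A [filter_config()].
#' @return Candidate subset of `records`.
#' @export
select_candidates <- function(records, config = filter_config()) {
  af_m <- compute_af(records, "mutant")$af
  af_a <- compute_af(records, "azygous")$af
  keep_m <- !is.na(af_m) & af_m >= config$mutant_af_min - config$mutant_af_tolerance
  keep_a <- ifelse(is.na(af_a), config$azygous_missing == "keep",
                   af_a < config$azygous_af_max)
  keep <- keep_m & keep_a
  if (config$require_absent_in_wildtype) {
    af_w <- compute_af(records, "wildtype")$af
    # a site with no usable wild-type reads carries no evidence of
    # presence, so it is not excluded
    keep <- keep & (is.na(af_w) | af_w <= config$wildtype_af_max)
  }
  subset_variants(records, keep)
}

#' Linkage consistency of one candidate with its neighbourhood
#'
#' Fraction of other variants within `window_bp` of the candidate (same
#' chromosome) whose mutant-pool AF is at least 0.8; a truly linked
#' causal variant sits in a neighbourhood of near-fixed variants in the
#' mutant pool.  Returns `NA` when fewer than `min_neighbors`
#' neighbours are available.
#'
#' @param records All (quality-filtered) `pool_variants`, any order.
#' @param chrom,pos Candidate coordinates.
#' @param window_bp Half-window in bp.
#' @param min_neighbors Minimum neighbour count for a defined score.
#' @param af_high Neighbour AF threshold (default 0.8).
#' @return Score in `[0, 1]`, or `NA`.
#' @export
linkage_consistency <- function(records, chrom, pos, window_bp,
                                min_neighbors = 3L, af_high = 0.8) {
  af <- compute_af(records, "mutant")
  nb <- af$chrom == chrom & abs(af$pos - pos) <= window_bp & af$pos != pos
  nb_af <- af$af[nb]
  nb_af <- nb_af[!is.na(nb_af)]
  if (length(nb_af) < min_neighbors) return(NA_real_)
  mean(nb_af >= af_high)
}

#' Attach linkage scores to a candidate table
#'
#' @param candidates Candidate `pool_variants`.
#' @param records Background records used for the neighbourhood.
#' @inheritParams linkage_consistency
#' @return `candidates` with an added `linkage_score` column.
#' @export
add_linkage_scores <- function(candidates, records, window_bp,
                               min_neighbors = 3L, af_high = 0.8) {
  candidates$linkage_score <- vapply(seq_len(nrow(candidates)), function(i) {
    linkage_consistency(records, candidates$chrom[i], candidates$pos[i],
                        window_bp, min_neighbors, af_high)
  }, numeric(1))
  candidates
}
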