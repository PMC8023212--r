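# Windowed allele-frequency profiles along chromosomes and candidate-
# region delimitation: the mutant-pool AF plateaus near 1 around the
# causal locus and decays towards 0.5 with map distance; the region is
# the longest run of high-AF windows.

#' Windowed allele-frequency profile
#'
#' Windows tile each chromosome at a fixed step (0-based half-open
#' coordinates); a variant is counted in every overlapping window.
#' `mean_af` is missing for empty windows.  When `window_bp` is `NULL`
#' the window auto-scales to 1/20 of the chromosome length and the step
#' to 1/5 of the window (see the methods vignette for the choice).
#'
#' @param records `pool_variants` (typically quality-filtered).
#' @param chrom_lengths Named chromosome lengths in bp, or a genome.
#' @param pool Pool whose AF is profiled (default `"mutant"`).
#' @param window_bp,step_bp Window and step sizes in bp
#'   (`window_bp >= step_bp > 0`).
#' @return An `af_profile` data frame: `chrom`, `start`, `end` (0-based
#'   half-open), `mean_af`, `n_variants`.
#' @export
window_af_profile <- function(records, chrom_lengths, pool = "mutant",
                              window_bp = NULL, step_bp = NULL) {
  if (!is.numeric(chrom_lengths)) {
    chrom_lengths <- genome_lengths(as_genome(chrom_lengths))
  }
  af <- compute_af(records, pool)
  out <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    w <- if (is.null(window_bp)) as.integer(ceiling(len / 20)) else
      as.integer(window_bp)
    s <- if (is.null(step_bp)) as.integer(ceiling(w / 5)) else
      as.integer(step_bp)
    if (!(w >= s && s > 0L)) stop("need window_bp >= step_bp > 0")
    starts <- seq.int(0L, max(0L, len - 1L), by = s)
    ends <- pmin(starts + w, len)
    sel <- af$chrom == ch & !is.na(af$af)
    p <- af$pos[sel]
    v <- af$af[sel]
    nv <- integer(length(starts))
    mv <- rep(NA_real_, length(starts))
    for (i in seq_along(starts)) {
      # window [start, end) holds 1-based positions start+1 .. end
      inw <- p > starts[i] & p <= ends[i]
      nv[i] <- sum(inw)
      if (nv[i] > 0L) mv[i] <- mean(v[inw])
    }
    out[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                            mean_af = mv, n_variants = nv,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, pool = pool, class = c("af_profile", "data.frame"))
}

#' Delimit the candidate region from an AF profile
#'
#' The candidate is the longest maximal run of at least `min_windows`
#' consecutive windows with `mean_af >= af_threshold`; empty (missing)
#' windows break runs.  The peak is the midpoint of the window with the
#' maximal mean AF inside the run (ties: leftmost window); run-length
#' ties resolve to the leftmost run in profile order.
#'
#' @param profile An `af_profile`.
#' @param af_threshold Plateau threshold in `(0.5, 1]` (default 0.9).
#' @param min_windows Minimum run length in windows.
#' @return A `candidate_region` (list with `chrom`, `start`, `end`
#'   1-based inclusive, `peak_pos`, `peak_af`, `n_windows`), or `NULL`
#'   when no qualifying run exists.
#' @export
detect_peak_region <- function(profile, af_threshold = 0.9,
                               min_windows = 3L) {
  if (!(af_threshold > 0.5 && af_threshold <= 1)) {
    stop("af_threshold must lie in (0.5, 1]")
  }
  best <- NULL
  for (ch in unique(profile$chrom)) {
    pr <- profile[profile$chrom == ch, , drop = FALSE]
    ok <- !is.na(pr$mean_af) & pr$mean_af >= af_threshold
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values & r$lengths >= min_windows)
    for (ri in runs) {
      i1 <- starts[ri]
      i2 <- ends[ri]
      if (is.null(best) || (i2 - i1) > (best$i2 - best$i1)) {
        best <- list(pr = pr, i1 = i1, i2 = i2)
      }
    }
  }
  if (is.null(best)) return(NULL)
  pr <- best$pr
  idx <- best$i1:best$i2
  peak_i <- idx[which.max(pr$mean_af[idx])]
  region_start0 <- pr$start[best$i1]
  region_end0 <- pr$end[best$i2]
  one <- to_one_inclusive(region_start0, region_end0)
  structure(
    list(chrom = pr$chrom[1L],
         start = unname(one[1, "start"]), end = unname(one[1, "end"]),
         peak_pos = as.integer((pr$start[peak_i] + pr$end[peak_i]) %/% 2 + 1L),
         peak_af = pr$mean_af[peak_i],
         n_windows = length(idx)),
    class = "candidate_region"
  )
}

#' @export
print.candidate_region <- function(x, ...) {
  cat(sprintf(
    "<candidate_region> %s:%d-%d (%.2f Mb), peak %.3f at %s:%d, %d windows\n",
    x$chrom, x$start, x$end, (x$end - x$start + 1) / 1e6, x$peak_af,
    x$chrom, x$peak_pos, x$n_windows))
  invisible(x)
}

#' Report candidates inside a region, with an AF profile plot
#'
#' Writes a TSV of the candidates falling inside the region and (when
#' `plot_path` is given) a profile plot with horizontal guides at 1 and
#' 0.5 -- the expected mutant-pool AF at the causal locus and at
#' unlinked sites -- and the region shaded.
#'
#' @param region A `candidate_region` (or `NULL` for a region-less
#'   report).
#' @param candidates Candidate `pool_variants` (optionally with a
#'   `linkage_score` column).
#' @param profile The `af_profile` used for detection.
#' @param tsv_path,plot_path Optional output paths.
#' @return Data frame of in-region candidates, invisibly.
#' @export
region_report <- function(region, candidates, profile,
                          tsv_path = NULL, plot_path = NULL) {
  af_m <- compute_af(candidates, "mutant")$af
  af_a <- compute_af(candidates, "azygous")$af
  af_w <- compute_af(candidates, "wildtype")$af
  tab <- data.frame(
    chrom = candidates$chrom, pos = candidates$pos,
    ref = candidates$ref, alt = candidates$alt,
    af_mutant = af_m, af_azygous = af_a, af_wildtype = af_w,
    dp = pool_field(candidates, "mutant", "dp"),
    gq = pool_field(candidates, "mutant", "gq"),
    linkage_score = if ("linkage_score" %in% names(candidates)) {
      candidates$linkage_score
    } else {
      rep_len(NA_real_, nrow(candidates))
    },
    stringsAsFactors = FALSE
  )
  in_region <- if (is.null(region)) {
    rep(FALSE, nrow(tab))
  } else {
    tab$chrom == region$chrom & tab$pos >= region$start &
      tab$pos <= region$end
  }
  out <- tab[in_region, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(tsv_path)) {
    write.table(out, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(plot_path)) {
    pr <- as.data.frame(profile)
    pr$mid <- (pr$start + pr$end) / 2
    gg <- ggplot2::ggplot(pr[!is.na(pr$mean_af), ],
                          ggplot2::aes(x = .data$mid / 1e6,
                                       y = .data$mean_af)) +
      ggplot2::geom_hline(yintercept = c(1, 0.5), linetype = "dashed",
                          colour = "grey40") +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::geom_line(linewidth = 0.3, alpha = 0.6) +
      ggplot2::facet_wrap(~chrom, ncol = 1) +
      ggplot2::labs(x = "position (Mb)",
                    y = sprintf("%s-pool allele frequency",
                                attr(profile, "pool"))) +
      ggplot2::ylim(0, 1) +
      ggplot2::theme_bw()
    if (!is.null(region)) {
      shade <- data.frame(chrom = region$chrom, xmin = region$start / 1e6,
                          xmax = region$end / 1e6)
      gg <- gg + ggplot2::geom_rect(
        data = shade,
        ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax),
        ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "firebrick",
        inherit.aes = FALSE
      )
    }
    ggplot2::ggsave(plot_path, gg, width = 7, height = 2.5 +
                      2 * length(unique(pr$chrom)), dpi = 110)
  }
  invisible(out)
}
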