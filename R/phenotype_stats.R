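# Chlorophyll-fluorescence parameters, the Fv/Fm phenotype screen,
# Mendelian segregation testing, and the analytic pooled allele-
# frequency expectations for a single recessive locus in a selfed-F1
# (BC1F2) population -- the quantities the mapping logic is validated
# against.

check_pos <- function(x, name) {
  if (any(!is.na(x) & x <= 0)) stop("field '", name, "' must be positive")
}

#' Chlorophyll fluorescence parameters
#'
#' Computes, for each record, the parameters that can be formed from
#' the inputs present (`NA` inputs leave the dependent outputs `NA`):
#' \itemize{
#'   \item `fvfm = (fm - fo) / fm` -- maximum quantum efficiency of
#'     PSII (dark-adapted);
#'   \item `fvfm_prime = (fm_prime - fo_prime) / fm_prime`;
#'   \item `phi_psii = (fm_prime - f_prime) / fm_prime` -- PSII
#'     operating efficiency;
#'   \item `qp = (fm_prime - f_prime) / (fm_prime - fo_prime)` --
#'     photochemical quenching;
#'   \item `npq = fm / fm_prime - 1` -- non-photochemical quenching.
#' }
#'
#' @param fo,fm Dark-adapted minimal and maximal fluorescence
#'   (arbitrary units, `fm > fo > 0`).
#' @param f_prime,fo_prime,fm_prime Light-adapted steady-state, minimal
#'   and maximal fluorescence (`fm_prime > fo_prime > 0`,
#'   `fm_prime >= f_prime`).
#' @return Data frame with columns `fvfm`, `fvfm_prime`, `phi_psii`,
#'   `qp`, `npq`.
#' @export
fluorescence_params <- function(fo = NA_real_, fm = NA_real_,
                                f_prime = NA_real_, fo_prime = NA_real_,
                                fm_prime = NA_real_) {
  n <- max(lengths(list(fo, fm, f_prime, fo_prime, fm_prime)))
  fo <- rep_len(fo, n); fm <- rep_len(fm, n)
  f_prime <- rep_len(f_prime, n); fo_prime <- rep_len(fo_prime, n)
  fm_prime <- rep_len(fm_prime, n)
  check_pos(fo, "fo"); check_pos(fm, "fm")
  check_pos(fo_prime, "fo_prime"); check_pos(fm_prime, "fm_prime")
  dark <- !is.na(fo) & !is.na(fm)
  if (any(dark & fm <= fo)) stop("field 'fm' must exceed 'fo'")
  light <- !is.na(fo_prime) & !is.na(fm_prime)
  if (any(light & fm_prime <= fo_prime)) {
    stop("field 'fm_prime' must exceed 'fo_prime'")
  }
  steady <- !is.na(f_prime) & !is.na(fm_prime)
  if (any(steady & fm_prime < f_prime)) {
    stop("field 'fm_prime' must be at least 'f_prime'")
  }
  data.frame(
    fvfm = (fm - fo) / fm,
    fvfm_prime = (fm_prime - fo_prime) / fm_prime,
    phi_psii = (fm_prime - f_prime) / fm_prime,
    qp = (fm_prime - f_prime) / (fm_prime - fo_prime),
    npq = fm / fm_prime - 1
  )
}

#' Classify the low-quantum-yield phenotype from Fv/Fm
#'
#' An individual is called `mutant` when its dark-adapted Fv/Fm falls
#' strictly below the cutoff (boundary value itself is
#' `wildtype-like`).  The default cutoff of 0.6 separates plants whose
#' PSII quantum yield collapses under low-CO2 screening from those that
#' retain it.
#'
#' @param fvfm Numeric vector in (0, 1).
#' @param cutoff Classification cutoff (default 0.6).
#' @return Character vector `"mutant"` / `"wildtype-like"`.
#' @export
classify_phenotype <- function(fvfm, cutoff = 0.6) {
  if (any(is.na(fvfm)) || any(fvfm <= 0) || any(fvfm >= 1)) {
    stop("fvfm values must lie in (0, 1)")
  }
  ifelse(fvfm < cutoff, "mutant", "wildtype-like")
}

#' Chi-square test of Mendelian segregation
#'
#' Pearson chi-square (1 df) of the observed mutant count against the
#' expected recessive fraction; for a single recessive allele in a
#' selfed-F1 population the expectation is 1/4.
#'
#' @param n_mutant,n_total Observed counts.
#' @param expected_fraction Expected mutant fraction (default 0.25).
#' @param correct Apply the Yates continuity correction (off by
#'   default; the design operates at n around 300).
#' @return Object of class `segregation_result`: `n_mutant`, `n_total`,
#'   `observed_fraction`, `chi_square`, `p_value`.
#' @export
segregation_test <- function(n_mutant, n_total, expected_fraction = 0.25,
                             correct = FALSE) {
  stopifnot(n_total >= 1, n_mutant >= 0, n_mutant <= n_total)
  obs <- c(n_mutant, n_total - n_mutant)
  exp_ <- n_total * c(expected_fraction, 1 - expected_fraction)
  dev <- abs(obs - exp_)
  if (correct) dev <- pmax(0, dev - 0.5)
  chi <- sum(dev^2 / exp_)
  structure(
    list(n_mutant = n_mutant, n_total = n_total,
         observed_fraction = n_mutant / n_total,
         chi_square = chi,
         p_value = pchisq(chi, df = 1, lower.tail = FALSE)),
    class = "segregation_result"
  )
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf(
    "<segregation_result> %d/%d mutant (%.1f%%), chi-square = %.3f, p = %.3g\n",
    x$n_mutant, x$n_total, 100 * x$observed_fraction, x$chi_square,
    x$p_value))
  invisible(x)
}

#' Expected pooled allele frequency at a linked marker
#'
#' For a single recessive causal locus in a selfed-F1 (BC1F2)
#' population with perfect phenotype selection, the expected frequency
#' of the mutant-line allele at a marker at recombination fraction `r`
#' from the causal locus is `1 - r` in the homozygous-mutant pool,
#' `(1 + r) / 3` in the azygous pool (1 homozygous reference : 2
#' heterozygous at the causal locus), and 0 in the un-mutagenized
#' wild-type pool.  At `r = 0` these give the signature values 1 and
#' 1/3 (~0.33).
#'
#' @param pool `"mutant"`, `"azygous"` or `"wildtype"`.
#' @param r Recombination fraction(s) in `[0, 0.5]`.
#' @return Expected allele frequency (vectorized over `r`).
#' @export
expected_pool_af <- function(pool = c("mutant", "azygous", "wildtype"), r) {
  pool <- match.arg(pool)
  if (any(r < 0 | r > 0.5)) {
    stop("recombination fraction r must lie in [0, 0.5]")
  }
  switch(pool,
         mutant = 1 - r,
         azygous = (1 + r) / 3,
         wildtype = rep(0, length(r)))
}

#' Haldane map function
#'
#' Recombination fraction for a map distance `d` in Morgans under the
#' no-interference (Poisson crossover) model: `(1 - exp(-2 d)) / 2`.
#'
#' @param d Map distance in Morgans.
#' @return Recombination fraction in `[0, 0.5)`.
#' @export
haldane_r <- function(d) {
  stopifnot(all(d >= 0))
  (1 - exp(-2 * d)) / 2
}
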