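# Dry-matter carbon isotope composition and discrimination.  The API
# works in dimensionless fractions throughout; per-mil is a
# presentation unit handled only by the explicit converters, which
# prevents the classic thousand-fold unit error.

#' Carbon isotope composition from molar ratios
#'
#' `delta_p = Rp / Rs - 1`, the 13C/12C composition of a sample
#' relative to the PDB standard, as a dimensionless fraction.
#'
#' @param rp Molar 13C/12C ratio of the plant sample (> 0).
#' @param rs Molar 13C/12C ratio of the PDB standard (> 0).
#' @return Composition as a fraction (multiply by 1000 for per mil).
#' @export
delta_from_ratio <- function(rp, rs) {
  if (any(rp <= 0) || any(rs <= 0)) {
    stop("molar abundance ratios must be positive")
  }
  rp / rs - 1
}

#' Molar ratio from an isotope composition
#'
#' Inverse of [delta_from_ratio()]: `Rp = (1 + delta) * Rs`.
#'
#' @param delta Composition as a fraction (> -1).
#' @param rs Standard ratio (> 0).
#' @return Molar ratio.
#' @export
ratio_from_delta <- function(delta, rs) {
  if (any(rs <= 0)) stop("molar abundance ratios must be positive")
  if (any(delta <= -1)) stop("delta must exceed -1")
  (1 + delta) * rs
}

#' Carbon isotope discrimination
#'
#' `Delta = (delta_a - delta_p) / (1 + delta_p)`, algebraically equal
#' to `Ra / Rp - 1` when both compositions are expressed against the
#' same standard.  The default air composition is -8 per mil
#' (delta_a = -0.008), the approximate 13C/12C composition of free
#' atmospheric CO2.
#'
#' @param delta_p Plant composition as a fraction.
#' @param delta_a Air composition as a fraction (default -0.008).
#' @return Discrimination as a fraction (use [as_permil()] to format).
#' @export
discrimination <- function(delta_p, delta_a = -0.008) {
  if (any(delta_p <= -1)) stop("delta_p must exceed -1")
  (delta_a - delta_p) / (1 + delta_p)
}

#' Convert a fraction to per mil
#' @param x Dimensionless fraction.
#' @return `x * 1000`.
#' @export
as_permil <- function(x) x * 1000

#' Convert per mil to a fraction
#' @param x Value in per mil.
#' @return `x / 1000`.
#' @export
from_permil <- function(x) x / 1000
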