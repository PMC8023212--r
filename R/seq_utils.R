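# Low-level sequence helpers shared by the simulator and the annotator.
# The codon table is deliberately hard-coded (nuclear plant genes use the
# standard code) and is cross-checked against an independent published
# table in the test suite.

#' Standard genetic code
#'
#' Named character vector mapping each of the 64 DNA codons to a
#' single-letter amino acid, with `"*"` for the three stop codons.
#'
#' @format Named character vector of length 64.
#' @export
CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Split a coding sequence into codons
#' @param seq Character scalar, DNA over ACGT with length divisible by 3.
#' @return Character vector of 3-mers.
#' @export
codons_of <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) {
    stop("coding sequence length ", n, " is not divisible by 3")
  }
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate a coding sequence with the standard genetic code
#'
#' @param seq Character scalar, spliced CDS in translation orientation.
#' @return Character scalar protein, with `"*"` for stops.
#' @export
translate_cds <- function(seq) {
  cod <- codons_of(toupper(seq))
  aa <- CODON_TABLE[cod]
  if (anyNA(aa)) {
    stop("unknown codon '", cod[which(is.na(aa))[1L]], "'")
  }
  paste(aa, collapse = "")
}

#' Reverse-complement a DNA string
#' @param seq Character scalar over ACGTN (case-insensitive).
#' @return Character scalar.
#' @export
revcomp <- function(seq) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", seq)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

comp_base <- function(base) chartr("ACGT", "TGCA", base)

# One-based inclusive (on-disk GFF3/VCF convention) -> 0-based half-open.
to_zero_half_open <- function(start1, end1) {
  cbind(start = start1 - 1L, end = end1)
}

# 0-based half-open -> 1-based inclusive for reporting.
to_one_inclusive <- function(start0, end0) {
  cbind(start = start0 + 1L, end = end0)
}
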