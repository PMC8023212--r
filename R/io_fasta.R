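# FASTA input/output.  Reading is done line by line so that malformed
# files can be rejected with the offending line number; the in-memory
# representation is a Biostrings::DNAStringSet ("Genome" throughout the
# package), which also handles wrapped output.

#' Read a reference genome from FASTA
#'
#' Parsing is case-insensitive; sequences are stored upper-case.  Only
#' `A`, `C`, `G`, `T`, `N` are accepted.  Record names are the first
#' whitespace-delimited token of the header.
#'
#' @param path Path to a plain-text FASTA file.
#' @return A [Biostrings::DNAStringSet] with unique names.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("FASTA file '", path, "' is empty")
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L]) {
    stop("FASTA format error at line ", lineno[1L],
         ": expected a '>' header line")
  }
  bad <- !is_hdr & grepl("[^ACGTNacgtn]", lines)
  if (any(bad)) {
    stop("FASTA format error at line ", lineno[which(bad)[1L]],
         ": non-ACGTN character in sequence")
  }
  rec <- cumsum(is_hdr)
  nms <- sub("\\s.*$", "", sub("^>", "", lines[is_hdr]))
  if (anyDuplicated(nms)) {
    stop("duplicate FASTA record name '", nms[duplicated(nms)][1L], "'")
  }
  body <- split(lines[!is_hdr], factor(rec[!is_hdr], levels = seq_along(nms)))
  seqs <- vapply(body, function(x) toupper(paste(x, collapse = "")),
                 character(1))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("empty record \"", nms[which(empty)[1L]], "\" in FASTA file")
  }
  Biostrings::DNAStringSet(stats::setNames(seqs, nms))
}

#' Write a genome to FASTA
#'
#' @param genome A [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @param line_width Wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, line_width = 60L) {
  genome <- as_genome(genome)
  Biostrings::writeXStringSet(genome, filepath = path, width = line_width)
  invisible(path)
}

# Coerce named character vectors to the DNAStringSet container.
as_genome <- function(genome) {
  if (is.character(genome)) {
    if (is.null(names(genome))) stop("genome sequences must be named")
    genome <- Biostrings::DNAStringSet(genome)
  }
  if (!inherits(genome, "DNAStringSet")) {
    stop("genome must be a DNAStringSet or a named character vector")
  }
  genome
}

genome_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

chrom_string <- function(genome, chrom) {
  if (!chrom %in% names(genome)) stop("unknown chromosome '", chrom, "'")
  as.character(genome[[chrom]])
}
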