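#' Read a mitochondrial reference sequence
#'
#' Loads a single-sequence FASTA and returns the sequence as an uppercase
#' character scalar (positions index directly into it with `substr`).
#'
#' @param path FASTA file with one sequence.
#' @return character scalar.
#' @export
readMitoReference <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L) stop("expected a single-sequence FASTA")
  toupper(as.character(ss[[1L]]))
}

#' Packaged synthetic reference sequence
#'
#' A deterministic synthetic 16,569 bp stand-in for the rCRS with realistic
#' base composition and the conventional N placeholder at position 3107.
#' It supports simulation and exercises the annotation machinery; analyses
#' of real samples should supply the true rCRS via [readMitoReference()].
#'
#' @return character scalar of length-16569 sequence.
#' @export
defaultMitoReference <- function() {
  if (is.null(.pkgEnv$reference))
    .pkgEnv$reference <- readMitoReference(.extdata("synthetic_mt_reference.fasta"))
  .pkgEnv$reference
}

.refSlice <- function(refSeq, from, to) substr(refSeq, from, to)

.complement <- function(x) chartr("ACGTN", "TGCAN", x)

.revcomp <- function(x) {
  paste(rev(strsplit(.complement(x), "")[[1L]]), collapse = "")
}

.mitoCode <- function() {
  if (is.null(.pkgEnv$code))
    .pkgEnv$code <- Biostrings::getGeneticCode("2")  # vertebrate mitochondrial
  .pkgEnv$code
}
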