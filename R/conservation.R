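#' Multi-species alignment container
#'
#' A light container for an aligned set of species sequences (nucleotide or
#' amino acid), the first row being the human/reference sequence.  The
#' reference row may itself contain gap columns; `refStart` gives the
#' reference coordinate of its first ungapped symbol so that alignments
#' covering a sub-region can be queried in genome (or protein) coordinates.
#'
#' @param seqs named character vector of aligned sequences (equal lengths);
#'   first element is the reference species.
#' @param level `"nucleotide"` or `"amino_acid"`.
#' @param refStart reference coordinate of the first ungapped reference
#'   symbol (default 1).
#' @return an object of class `SpeciesAlignment`.
#' @export
speciesAlignment <- function(seqs, level = c("nucleotide", "amino_acid"),
                             refStart = 1L) {
  level <- match.arg(level)
  if (length(seqs) < 2L) stop("alignment needs at least 2 species")
  if (length(unique(nchar(seqs))) != 1L)
    stop("aligned sequences must have equal length")
  mat <- do.call(rbind, strsplit(toupper(unname(seqs)), ""))
  rownames(mat) <- names(seqs) %||% paste0("sp", seq_along(seqs))
  structure(list(mat = mat, level = level, refStart = as.integer(refStart),
                 species = rownames(mat)),
            class = "SpeciesAlignment")
}

#' @rdname speciesAlignment
#' @param path aligned multi-FASTA; if the first (reference) header carries
#'   a `/start-end` suffix, `start` is taken as `refStart`.
#' @export
readSpeciesAlignment <- function(path, level = c("nucleotide", "amino_acid")) {
  ss <- Biostrings::readBStringSet(path)
  nm <- names(ss)
  refStart <- 1L
  m <- regmatches(nm[1L], regexec("^(.*)/([0-9]+)-[0-9]+\\s*$", nm[1L]))[[1L]]
  if (length(m) == 3L) {
    nm[1L] <- m[2L]
    refStart <- as.integer(m[3L])
  }
  speciesAlignment(setNames(as.character(ss), nm), level = level,
                   refStart = refStart)
}

#' @method print SpeciesAlignment
#' @export
print.SpeciesAlignment <- function(x, ...) {
  cat("SpeciesAlignment:", nrow(x$mat), "species x", ncol(x$mat),
      "columns (", x$level, "), reference", x$species[1L],
      "starting at", x$refStart, "\n")
  invisible(x)
}

# column index of reference coordinate `coord`, NA when outside the alignment
.refColumn <- function(aln, coord) {
  ref <- aln$mat[1L, ]
  ungapped <- cumsum(ref != "-")
  target <- coord - aln$refStart + 1L
  idx <- which(ref != "-" & ungapped == target)
  if (length(idx)) idx[1L] else NA_integer_
}

#' Conservation index of an alignment column
#'
#' The proportion of non-reference species whose aligned symbol equals the
#' reference (wild-type) symbol at that column.  Gaps and ambiguity codes
#' count as mismatches; comparison is case-insensitive.  The reference row
#' is excluded from numerator and denominator by default
#' (`includeReference = TRUE` switches to counting it in both, for the
#' alternative all-species convention).
#'
#' @param aln a [speciesAlignment()].
#' @param column 1-based alignment column index.
#' @param wildType the expected reference symbol at the column (checked for
#'   consistency).
#' @param includeReference include the reference row in the denominator.
#' @return fraction in `[0, 1]`.
#' @examples
#' a <- speciesAlignment(c(hum = "ACGT", sp1 = "ACGT", sp2 = "ATGT"))
#' conservationIndex(a, 2, "C")  # 0.5
#' @export
conservationIndex <- function(aln, column, wildType,
                              includeReference = FALSE) {
  stopifnot(inherits(aln, "SpeciesAlignment"))
  if (column < 1L || column > ncol(aln$mat))
    stop("column outside the alignment")
  col <- aln$mat[, column]
  wildType <- toupper(wildType)
  if (col[1L] != wildType)
    stop("wild type '", wildType, "' does not match reference symbol '",
         col[1L], "' at column ", column)
  rows <- if (includeReference) col else col[-1L]
  sum(rows == wildType) / length(rows)
}

#' Conservation filter for a variant set
#'
#' Annotates each variant with its conservation index and applies the
#' strict CI > threshold rule (default 75%).  Nonsynonymous protein
#' variants are evaluated at the amino-acid level (per-gene alignments in
#' `alnAA`, indexed by codon number); all other variants at the nucleotide
#' level against `alnNT` in genome coordinates.  A variant whose site is
#' not covered, or falls on a reference-gap column, is flagged
#' `no_ci = TRUE` and never passes silently.
#'
#' @param variants character vector of `pos_REF>ALT` labels, or the
#'   `data.frame` returned by [annotateVariants()].
#' @param alnNT nucleotide [speciesAlignment()] (or `NULL`).
#' @param alnAA named list of per-gene amino-acid alignments (or `NULL`).
#' @param gm a [MitoGenomeMap-class].
#' @param refSeq reference sequence.
#' @param threshold strict lower bound on CI (default 0.75).
#' @param includeReference see [conservationIndex()].
#' @return `data.frame`: `variant`, `level`, `ci`, `no_ci`, `pass`.
#' @export
conservedFilter <- function(variants, alnNT = NULL, alnAA = NULL,
                            gm = defaultGenomeMap(),
                            refSeq = defaultMitoReference(),
                            threshold = 0.75, includeReference = FALSE) {
  ann <- if (is.data.frame(variants)) variants
         else annotateVariants(variants, gm, refSeq)
  f <- features(gm)
  n <- nrow(ann)
  ci <- rep(NA_real_, n)
  level <- character(n)
  for (i in seq_len(n)) {
    protein_aa <- identical(ann$region_kind[i], "protein") &&
      identical(ann$coding_effect[i], "nonsynonymous") &&
      !is.na(ann$ref_aa[i])
    if (protein_aa) {
      level[i] <- "amino_acid"
      a <- alnAA[[ann$region[i]]]
      if (!is.null(a)) {
        row <- f[match(ann$region[i], f$name), ]
        off <- if (row$strand == "heavy") ann$position[i] - row$start
               else row$end - ann$position[i]
        col <- .refColumn(a, off %/% 3L + 1L)
        if (!is.na(col) && a$mat[1L, col] == ann$ref_aa[i])
          ci[i] <- conservationIndex(a, col, ann$ref_aa[i], includeReference)
      }
    } else {
      level[i] <- "nucleotide"
      if (!is.null(alnNT)) {
        col <- .refColumn(alnNT, ann$position[i])
        wt <- substr(ann$ref[i], 1L, 1L)
        if (!is.na(col) && alnNT$mat[1L, col] == wt)
          ci[i] <- conservationIndex(alnNT, col, wt, includeReference)
      }
    }
  }
  data.frame(variant = ann$variant, level = level, ci = ci,
             no_ci = is.na(ci),
             pass = !is.na(ci) & ci > threshold,
             stringsAsFactors = FALSE)
}
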