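#' Read a mitochondrial gene map
#'
#' Reads a tab-separated feature table (columns `name`, `start`, `end`,
#' `strand`, `kind`, `wrap`) into a [MitoGenomeMap-class].  Coordinates are
#' 1-based inclusive; a wrapping feature (control region) has `wrap = 1`
#' and `start > end`.  Protein features whose oriented length is not a
#' multiple of 3 are flagged as carrying an incomplete stop codon
#' (completed by polyadenylation in vivo), the usual situation for ND1,
#' ND2, ND3, ND4, COX3 and CYTB.
#'
#' @param path path to the TSV file.
#' @param genomeLength genome length in bases (rCRS: 16569).
#' @return a validated `MitoGenomeMap`.
#' @export
readGenomeMap <- function(path, genomeLength = 16569L) {
  f <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  f$wrap <- as.logical(f$wrap)
  f$start <- as.integer(f$start)
  f$end <- as.integer(f$end)
  len <- .featureLength(f$start, f$end, f$wrap, as.integer(genomeLength))
  f$incomplete_stop <- f$kind == "protein" & len %% 3L != 0L
  new("MitoGenomeMap", features = f, genomeLength = as.integer(genomeLength))
}

#' Packaged rCRS gene map
#'
#' The published rCRS coordinates of the 37 mitochondrial genes, the light
#' strand replication origin (OL) and the control region (wrapping
#' 16024-576).  Overlapping gene pairs (e.g. ATP8/ATP6, ND4L/ND4) are kept
#' as printed; see [assignRegion()] for how overlaps are attributed.
#'
#' @return a `MitoGenomeMap`.
#' @export
defaultGenomeMap <- function() {
  if (is.null(.pkgEnv$genomeMap))
    .pkgEnv$genomeMap <- readGenomeMap(.extdata("rcrs_gene_map.tsv"))
  .pkgEnv$genomeMap
}

.inFeature <- function(position, start, end, wrap) {
  if (wrap) position >= start | position <= end
  else position >= start & position <= end
}

#' Map genome positions to features
#'
#' Returns, for each 1-based position, the name of the containing feature,
#' or `"intergenic"` when no feature covers it.  Where features overlap
#' (the mitochondrial genome has several overlapping genes, e.g.
#' ATP8/ATP6), the position is attributed to the *first* feature in map
#' order; `featureOverlaps()` lists the ambiguous pairs so the choice is
#' auditable, and `all = TRUE` returns every containing feature.
#'
#' @param position integer vector of 1-based positions.
#' @param gm a [MitoGenomeMap-class]; defaults to the packaged rCRS map.
#' @param all if `TRUE`, return a list of all containing feature names per
#'   position instead of the first.
#' @return character vector of feature names (or a list when `all = TRUE`).
#' @examples
#' assignRegion(3010)   # "16S rRNA"
#' assignRegion(16569)  # "D-loop" (control region wraps the origin)
#' @export
assignRegion <- function(position, gm = defaultGenomeMap(), all = FALSE) {
  position <- as.integer(position)
  L <- genomeLength(gm)
  if (any(is.na(position)) || any(position < 1L | position > L))
    stop("position out of range [1, ", L, "]")
  f <- features(gm)
  hit <- matrix(FALSE, length(position), nrow(f))
  for (j in seq_len(nrow(f)))
    hit[, j] <- .inFeature(position, f$start[j], f$end[j], f$wrap[j])
  if (all)
    return(lapply(seq_along(position),
                  function(i) f$name[hit[i, ]]))
  idx <- apply(hit, 1L, function(h) if (any(h)) which(h)[1L] else NA_integer_)
  ifelse(is.na(idx), "intergenic", f$name[idx])
}

#' @rdname assignRegion
#' @return `featureOverlaps()` returns a `data.frame` of overlapping
#'   feature pairs with the positions they share; the first-named feature
#'   of each pair is the one `assignRegion()` reports.
#' @export
featureOverlaps <- function(gm = defaultGenomeMap()) {
  f <- features(gm)
  L <- genomeLength(gm)
  cover <- lapply(seq_len(nrow(f)), function(j) {
    if (f$wrap[j]) c(f$start[j]:L, 1L:f$end[j]) else f$start[j]:f$end[j]
  })
  out <- list()
  for (i in seq_len(nrow(f) - 1L))
    for (j in seq(i + 1L, nrow(f))) {
      shared <- intersect(cover[[i]], cover[[j]])
      if (length(shared))
        out[[length(out) + 1L]] <- data.frame(
          first = f$name[i], second = f$name[j],
          from = min(shared), to = max(shared), n_shared = length(shared),
          stringsAsFactors = FALSE)
    }
  if (!length(out))
    return(data.frame(first = character(0), second = character(0),
                      from = integer(0), to = integer(0),
                      n_shared = integer(0)))
  do.call(rbind, out)
}
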