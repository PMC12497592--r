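#' Predict the functional effect of a variant
#'
#' Builds the affected codon in the reading frame of the containing protein
#' feature (light-strand features are read reverse-complemented) and
#' translates it with the vertebrate mitochondrial genetic code.  Variants
#' outside protein features are `"noncoding"`; indels inside protein
#' features whose length change is not a multiple of 3 are
#' `"frameshift"` (in-frame indels are reported `"nonsynonymous"`).
#' Codons in the trailing incomplete stop of a gene are completed with
#' `A` (mirroring post-transcriptional polyadenylation) before
#' translation.
#'
#' @param variant a `pos_REF>ALT` label or a one-row data.frame from
#'   [parseVariantLabel()].
#' @param gm a [MitoGenomeMap-class].
#' @param refSeq reference sequence (character scalar, see
#'   [readMitoReference()]); the variant's `ref` must match it.
#' @return a list with `region`, `region_kind`, `coding_effect`
#'   (`synonymous`, `nonsynonymous`, `frameshift`, `stop_gain`,
#'   `noncoding`), `ref_aa`, `alt_aa` and `substitution_class`.
#' @examples
#' eff <- predictEffect("3010_G>A", defaultGenomeMap(), defaultMitoReference())
#' eff$region        # "16S rRNA"
#' eff$coding_effect # "noncoding"
#' @export
predictEffect <- function(variant, gm = defaultGenomeMap(),
                          refSeq = defaultMitoReference()) {
  v <- if (is.character(variant)) parseVariantLabel(variant) else variant
  stopifnot(nrow(v) == 1L)
  if (nchar(refSeq) != genomeLength(gm))
    stop("reference sequence length does not match the genome map")
  obs <- .refSlice(refSeq, v$position, v$position + nchar(v$ref) - 1L)
  if (obs != v$ref)
    stop("variant ref '", v$ref, "' does not match reference '", obs,
         "' at position ", v$position)
  region <- assignRegion(v$position, gm)
  f <- features(gm)
  kind <- if (region == "intergenic") "noncoding"
          else f$kind[match(region, f$name)]
  sub_class <- classifySubstitution(v$ref, v$alt)
  out <- list(region = region, region_kind = kind,
              coding_effect = "noncoding", ref_aa = NA_character_,
              alt_aa = NA_character_, substitution_class = sub_class)
  if (kind != "protein") return(out)
  if (v$var_class != "substitution") {
    shift <- abs(nchar(v$alt) - nchar(v$ref))
    out$coding_effect <- if (shift %% 3L != 0L) "frameshift" else "nonsynonymous"
    return(out)
  }
  row <- f[match(region, f$name), ]
  cod <- .affectedCodon(v$position, v$alt, row, refSeq)
  code <- .mitoCode()
  ref_aa <- unname(code[cod$ref])
  alt_aa <- unname(code[cod$alt])
  out$ref_aa <- ref_aa
  out$alt_aa <- alt_aa
  out$coding_effect <-
    if (is.na(ref_aa) || is.na(alt_aa)) NA_character_
    else if (ref_aa == alt_aa) "synonymous"
    else if (alt_aa == "*") "stop_gain"
    else "nonsynonymous"
  out
}

# reference and mutated codon containing `position` in feature `row`
.affectedCodon <- function(position, alt, row, refSeq) {
  if (row$strand == "heavy") {
    offset <- position - row$start
    ci <- offset %/% 3L
    p <- row$start + ci * 3L + 0:2
    base <- vapply(p, function(x)
      if (x > row$end) "A" else .refSlice(refSeq, x, x), "")  # poly-A completion
    k <- offset %% 3L + 1L
    ref_cod <- paste(base, collapse = "")
    base[k] <- toupper(alt)
    list(ref = ref_cod, alt = paste(base, collapse = ""))
  } else {
    offset <- row$end - position
    ci <- offset %/% 3L
    p <- row$end - (ci * 3L + 0:2)
    base <- vapply(p, function(x)
      if (x < row$start) "A" else .complement(.refSlice(refSeq, x, x)), "")
    k <- offset %% 3L + 1L
    ref_cod <- paste(base, collapse = "")
    base[k] <- .complement(toupper(alt))
    list(ref = ref_cod, alt = paste(base, collapse = ""))
  }
}

#' Translate a protein feature of the reference
#'
#' Extracts the feature's sequence (reverse-complemented for light-strand
#' features), completes a trailing incomplete stop codon with `A`, and
#' translates it with the vertebrate mitochondrial genetic code via
#' Biostrings.  Used as an independent full-gene oracle for
#' [predictEffect()].
#'
#' @param name feature name.
#' @param gm a [MitoGenomeMap-class].
#' @param refSeq reference sequence (character scalar).
#' @return character scalar amino-acid sequence (stop as `*`).
#' @export
translateFeature <- function(name, gm = defaultGenomeMap(),
                             refSeq = defaultMitoReference()) {
  f <- features(gm)
  row <- f[match(name, f$name), ]
  if (is.na(row$start)) stop("unknown feature: ", name)
  if (row$kind != "protein") stop("feature is not protein-coding: ", name)
  nt <- .refSlice(refSeq, row$start, row$end)
  if (row$strand == "light") nt <- .revcomp(nt)
  pad <- (3L - nchar(nt) %% 3L) %% 3L
  nt <- paste0(nt, strrep("A", pad))
  as.character(Biostrings::translate(
    Biostrings::DNAString(nt), genetic.code = .mitoCode()))
}

#' Annotate a set of variants
#'
#' Vectorized wrapper around [assignRegion()], [classifySubstitution()] and
#' [predictEffect()].
#'
#' @param variants character vector of `pos_REF>ALT` labels.
#' @inheritParams predictEffect
#' @return `data.frame` with one row per variant: parsed fields plus
#'   `region`, `region_kind`, `coding_effect`, `ref_aa`, `alt_aa`,
#'   `substitution_class`.
#' @export
annotateVariants <- function(variants, gm = defaultGenomeMap(),
                             refSeq = defaultMitoReference()) {
  v <- parseVariantLabel(variants)
  eff <- lapply(seq_len(nrow(v)), function(i)
    predictEffect(v[i, , drop = FALSE], gm, refSeq))
  cbind(v,
        region = vapply(eff, `[[`, "", "region"),
        region_kind = vapply(eff, `[[`, "", "region_kind"),
        coding_effect = vapply(eff, function(e)
          ifelse(is.na(e$coding_effect), NA_character_, e$coding_effect), ""),
        ref_aa = vapply(eff, function(e) e$ref_aa %||% NA_character_, ""),
        alt_aa = vapply(eff, function(e) e$alt_aa %||% NA_character_, ""),
        substitution_class = vapply(eff, `[[`, "", "substitution_class"),
        stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a
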