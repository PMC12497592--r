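#' Parse and format variant labels
#'
#' Variant labels follow the MitoMap convention `pos_REF>ALT`, e.g.
#' `"3010_G>A"` for a substitution and `"302_A>AC"` for an insertion after
#' the anchor base at 302.  `parseVariantLabel()` splits labels into their
#' components and classifies each as substitution, insertion or deletion;
#' `variantLabel()` is the inverse.
#'
#' @param label character vector of `pos_REF>ALT` labels.
#' @return `data.frame` with columns `variant`, `position`, `ref`, `alt`,
#'   `var_class`.
#' @examples
#' parseVariantLabel(c("3010_G>A", "302_A>AC", "8281_AC>A"))
#' @export
parseVariantLabel <- function(label) {
  m <- regmatches(label, regexec("^([0-9]+)_([ACGTN]+)>([ACGTN]+)$", label,
                                 ignore.case = TRUE))
  bad <- lengths(m) != 4L
  if (any(bad))
    stop("malformed variant label(s): ", paste(label[bad], collapse = ", "))
  position <- as.integer(vapply(m, `[`, "", 2L))
  ref <- toupper(vapply(m, `[`, "", 3L))
  alt <- toupper(vapply(m, `[`, "", 4L))
  data.frame(variant = label, position = position, ref = ref, alt = alt,
             var_class = .varClass(ref, alt), stringsAsFactors = FALSE)
}

.varClass <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "substitution",
         ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
}

#' @rdname parseVariantLabel
#' @param position,ref,alt variant components.
#' @export
variantLabel <- function(position, ref, alt) {
  sprintf("%d_%s>%s", as.integer(position), toupper(ref), toupper(alt))
}

#' Classify a substitution as transition, transversion or indel
#'
#' Single-base purine-to-purine or pyrimidine-to-pyrimidine changes are
#' transitions; purine-to-pyrimidine (or vice versa) are transversions;
#' anything involving a length change is an indel.
#'
#' @param ref,alt reference and alternate allele strings (vectorized).
#' @return character vector in `{"transition","transversion","indel"}`.
#' @examples
#' classifySubstitution("G", "A")  # transition
#' classifySubstitution("A", "T")  # transversion
#' classifySubstitution("A", "AC") # indel
#' @export
classifySubstitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  purine <- c("A", "G")
  single <- nchar(ref) == 1L & nchar(alt) == 1L & ref != alt
  same_type <- (ref %in% purine) == (alt %in% purine)
  ifelse(!single, "indel", ifelse(same_type, "transition", "transversion"))
}
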