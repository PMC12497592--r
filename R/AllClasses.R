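#' Mitochondrial genome feature map
#'
#' Ordered feature annotation of the circular mitochondrial reference:
#' 37 genes plus the control region.  Coordinates are 1-based inclusive on
#' the rCRS numbering; a feature that spans the circular origin (the
#' control region, 16024-576) carries `wrap = TRUE` and has `start > end`.
#'
#' @slot features `data.frame` with columns `name`, `start`, `end`,
#'   `strand` (`"heavy"`/`"light"`), `kind` (`"protein"`, `"tRNA"`,
#'   `"rRNA"`, `"control"`, `"noncoding"`) and logical `wrap`.
#' @slot genomeLength single positive integer, 16569 for the rCRS.
#'
#' @seealso [readGenomeMap()], [defaultGenomeMap()], [assignRegion()]
#' @export
setClass("MitoGenomeMap",
  representation(features = "data.frame", genomeLength = "integer"))

.featureKinds <- c("protein", "tRNA", "rRNA", "control", "noncoding")

.featureLength <- function(start, end, wrap, L) {
  ifelse(wrap, L - start + 1L + end, end - start + 1L)
}

setValidity("MitoGenomeMap", function(object) {
  f <- object@features
  L <- object@genomeLength
  msgs <- character(0)
  need <- c("name", "start", "end", "strand", "kind", "wrap")
  if (!all(need %in% names(f)))
    return(paste("features must have columns", paste(need, collapse = ", ")))
  if (length(L) != 1L || is.na(L) || L < 1L)
    msgs <- c(msgs, "genomeLength must be a single positive integer")
  if (anyDuplicated(f$name)) msgs <- c(msgs, "feature names must be unique")
  if (!all(f$kind %in% .featureKinds))
    msgs <- c(msgs, paste("kind must be one of",
                          paste(.featureKinds, collapse = ", ")))
  if (!all(f$strand %in% c("heavy", "light")))
    msgs <- c(msgs, "strand must be 'heavy' or 'light'")
  bad <- f$start < 1L | f$start > L | f$end < 1L | f$end > L
  if (any(bad))
    msgs <- c(msgs, paste("feature intervals outside [1, genomeLength]:",
                          paste(f$name[bad], collapse = ", ")))
  rev_ok <- f$wrap | f$start <= f$end
  if (!all(rev_ok))
    msgs <- c(msgs, paste("start > end without wrap flag:",
                          paste(f$name[!rev_ok], collapse = ", ")))
  prot <- f$kind == "protein"
  if (any(prot)) {
    len <- .featureLength(f$start, f$end, f$wrap, L)[prot]
    inc <- if ("incomplete_stop" %in% names(f)) f$incomplete_stop[prot]
           else len %% 3L != 0L
    bad <- len %% 3L != 0L & !inc
    if (any(bad))
      msgs <- c(msgs, paste("protein feature length not divisible by 3",
                            "without incomplete-stop flag:",
                            paste(f$name[prot][bad], collapse = ", ")))
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

setMethod("show", "MitoGenomeMap", function(object) {
  f <- object@features
  cat("MitoGenomeMap:", nrow(f), "features on a", object@genomeLength,
      "bp circular genome\n")
  cat("  kinds:", paste(sprintf("%s=%d", names(table(f$kind)),
                                as.integer(table(f$kind))), collapse = " "),
      "\n")
  if (any(f$wrap)) cat("  wrapping:", paste(f$name[f$wrap], collapse = ", "),
                       "\n")
})

#' Haplogroup phylotree
#'
#' A rooted hierarchy of haplogroup labels, each node carrying the set of
#' variants (as `pos_REF>ALT` labels) that arose on the branch leading to
#' it.  The *defining closure* of a node is the union of its own defining
#' variants and those of all its ancestors.
#'
#' @slot nodes `data.frame` with columns `haplogroup`, `parent` (`NA` for
#'   the root) and `defining_variants` (comma-separated labels).
#' @slot root the root haplogroup label.
#'
#' @seealso [readPhylotree()], [defaultPhylotree()], [assignHaplogroup()]
#' @export
setClass("Phylotree", representation(nodes = "data.frame", root = "character"))

setValidity("Phylotree", function(object) {
  n <- object@nodes
  msgs <- character(0)
  need <- c("haplogroup", "parent", "defining_variants")
  if (!all(need %in% names(n)))
    return(paste("nodes must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(n$haplogroup)) msgs <- c(msgs, "duplicate haplogroup labels")
  roots <- n$haplogroup[is.na(n$parent)]
  if (length(roots) != 1L) msgs <- c(msgs, "tree must have exactly one root")
  known <- n$parent %in% n$haplogroup | is.na(n$parent)
  if (!all(known))
    msgs <- c(msgs, paste("unknown parent labels:",
                          paste(unique(n$parent[!known]), collapse = ", ")))
  # acyclicity: walking up from every node must reach the root
  if (!length(msgs)) {
    parent <- setNames(n$parent, n$haplogroup)
    for (h in n$haplogroup) {
      seen <- character(0)
      cur <- h
      while (!is.na(parent[[cur]])) {
        if (cur %in% seen) return(paste("cycle through", cur))
        seen <- c(seen, cur)
        cur <- parent[[cur]]
      }
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

setMethod("show", "Phylotree", function(object) {
  nv <- length(unlist(strsplit(object@nodes$defining_variants[
    nzchar(object@nodes$defining_variants)], ",")))
  cat("Phylotree:", nrow(object@nodes), "haplogroups,", nv,
      "defining variants, root", object@root, "\n")
})

#' Case-control cohort of per-sample mtDNA calls
#'
#' Container pairing a long table of per-sample variant calls (with read
#' support, heteroplasmy fraction and state) with the sample-to-group
#' assignment.  Produced by [readCohortVCF()] or [simulateCohort()].
#'
#' @slot calls `data.frame` with columns `sample_id`, `variant`
#'   (`pos_REF>ALT` label), `position`, `ref`, `alt`, `alt_reads`,
#'   `total_reads`, `hf`, `state`.
#' @slot samples `data.frame` with columns `sample_id`, `group`
#'   (`"case"`/`"control"`).
#' @slot metadata list of provenance/truth information (simulation truth
#'   tables live here).
#'
#' @seealso [calls()], [sampleGroups()], [summarizeVariants()]
#' @export
setClass("MitoCohort",
  representation(calls = "data.frame", samples = "data.frame",
                 metadata = "list"))

setValidity("MitoCohort", function(object) {
  msgs <- character(0)
  cl <- object@calls; sm <- object@samples
  need_c <- c("sample_id", "variant", "alt_reads", "total_reads", "hf", "state")
  if (!all(need_c %in% names(cl)))
    return(paste("calls must have columns", paste(need_c, collapse = ", ")))
  if (!all(c("sample_id", "group") %in% names(sm)))
    return("samples must have columns sample_id, group")
  if (!all(sm$group %in% c("case", "control")))
    msgs <- c(msgs, "group must be 'case' or 'control'")
  if (anyDuplicated(sm$sample_id)) msgs <- c(msgs, "duplicate sample_ids")
  if (nrow(cl)) {
    if (!all(cl$sample_id %in% sm$sample_id))
      msgs <- c(msgs, "calls refer to samples absent from the sample table")
    if (any(cl$alt_reads > cl$total_reads))
      msgs <- c(msgs, "alt_reads must not exceed total_reads")
    ok_hf <- cl$total_reads == 0 |
      abs(cl$hf - cl$alt_reads / cl$total_reads) < 1e-9
    if (!all(ok_hf)) msgs <- c(msgs, "hf must equal alt_reads/total_reads")
    if (!all(cl$state %in% c("excluded", "heteroplasmic", "homoplasmic")))
      msgs <- c(msgs, "invalid call state")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

setMethod("show", "MitoCohort", function(object) {
  sm <- object@samples
  cat("MitoCohort:", nrow(sm), "samples (",
      sum(sm$group == "case"), "cases /", sum(sm$group == "control"),
      "controls ),", nrow(object@calls), "calls at",
      length(unique(object@calls$variant)), "variants\n")
})

#' @rdname MitoCohort-class
#' @param object,x a `MitoCohort`
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname MitoCohort-class
#' @export
setMethod("calls", "MitoCohort", function(x) x@calls)

#' @rdname MitoCohort-class
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname MitoCohort-class
#' @export
setMethod("sampleGroups", "MitoCohort", function(x) x@samples)

#' @rdname MitoCohort-class
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))

#' @rdname MitoCohort-class
#' @details `cohortTruth()` returns the simulation truth tables (`NULL` for
#'   cohorts read from a VCF).
#' @export
setMethod("cohortTruth", "MitoCohort", function(x) x@metadata$truth)

#' @rdname MitoGenomeMap-class
#' @param x a `MitoGenomeMap`
#' @export
setGeneric("features", function(x) standardGeneric("features"))

#' @rdname MitoGenomeMap-class
#' @export
setMethod("features", "MitoGenomeMap", function(x) x@features)

#' @rdname MitoGenomeMap-class
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' @rdname MitoGenomeMap-class
#' @export
setMethod("genomeLength", "MitoGenomeMap", function(x) x@genomeLength)
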