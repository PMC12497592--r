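#' Read a phylotree of haplogroup-defining variants
#'
#' TSV columns: `haplogroup`, `parent` (empty for the root),
#' `defining_variants` (comma-separated `pos_REF>ALT` labels).
#'
#' @param path TSV file.
#' @return a [Phylotree-class].
#' @export
readPhylotree <- function(path) {
  n <- read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  n$defining_variants[is.na(n$defining_variants)] <- ""
  new("Phylotree", nodes = n, root = n$haplogroup[is.na(n$parent)][1L])
}

#' Packaged synthetic phylotree
#'
#' A 33-node haplogroup hierarchy with realistic East-Asian labels
#' (macro-haplogroups M/N/R, the Table-style groups A, B, D4, D5, F, G,
#' M7, R, Z and their sub-lineages) but synthetic defining-variant sets
#' consistent with the packaged synthetic reference.  Suitable for
#' simulation and method validation, not for classifying real samples.
#'
#' @return a [Phylotree-class].
#' @export
defaultPhylotree <- function() {
  if (is.null(.pkgEnv$phylotree))
    .pkgEnv$phylotree <- readPhylotree(.extdata("synthetic_phylotree.tsv"))
  .pkgEnv$phylotree
}

.treeVars <- function(tree) {
  v <- strsplit(tree@nodes$defining_variants, ",", fixed = TRUE)
  names(v) <- tree@nodes$haplogroup
  v
}

#' Defining-variant closure and depth of each haplogroup
#'
#' The closure of a node is the union of the defining variants along its
#' path from the root; its depth is the number of edges on that path.
#'
#' @param tree a [Phylotree-class].
#' @return `haplogroupClosure()`: named list of character vectors;
#'   `haplogroupDepths()`: named integer vector.
#' @export
haplogroupClosure <- function(tree) {
  own <- .treeVars(tree)
  parent <- setNames(tree@nodes$parent, tree@nodes$haplogroup)
  closure <- list()
  expand <- function(h) {
    if (!is.null(closure[[h]])) return(closure[[h]])
    v <- own[[h]]
    if (!is.na(parent[[h]])) v <- union(expand(parent[[h]]), v)
    closure[[h]] <<- v
    v
  }
  for (h in tree@nodes$haplogroup) expand(h)
  closure[tree@nodes$haplogroup]
}

#' @rdname haplogroupClosure
#' @export
haplogroupDepths <- function(tree) {
  parent <- setNames(tree@nodes$parent, tree@nodes$haplogroup)
  vapply(tree@nodes$haplogroup, function(h) {
    d <- 0L
    while (!is.na(parent[[h]])) { d <- d + 1L; h <- parent[[h]] }
    d
  }, 0L)
}

#' Default hotspot mask
#'
#' Positions excluded from haplogroup scoring: the homopolymeric-tract
#' indel hotspots around 302-316 and 16180-16193, the 514-524 repeat,
#' the rCRS placeholder 3107, and the near-universal 16519.
#'
#' @return integer vector of positions.
#' @export
defaultHotspotMask <- function() {
  c(302L, 309L, 310L, 315L, 316L, 514L, 523L, 524L, 3107L,
    16182L, 16183L, 16189L, 16193L, 16519L)
}

#' Assign a haplogroup to a sample's variant set
#'
#' Scores every haplogroup `h` with defining closure `D_h` against the
#' sample's informative variant set with a symmetric (Kulczynski-style)
#' overlap score
#' `score(h) = ((|S ∩ D_h| / |D_h|) + (|S ∩ D_h| / |S_inf|)) / 2`,
#' where `S_inf` is the subset of the sample's variants that occur
#' anywhere in the tree (private variants outside the tree do not dilute
#' the score).  Variants at masked hotspot positions are removed first.
#' The best-scoring node wins; ties break towards the deeper node, then
#' lexicographically.  This is a deterministic, documented stand-in for
#' rank-based classifiers such as HaploGrep: the scientific weight of the
#' pipeline lies downstream in the association analysis.
#'
#' @param sampleVariants character vector of `pos_REF>ALT` labels.
#' @param tree a [Phylotree-class].
#' @param mask integer positions to exclude ([defaultHotspotMask()]).
#' @return list with `best`, `score`, `runner_up`, `margin`
#'   (`best = "unclassified"` when no variant matches the tree).
#' @export
assignHaplogroup <- function(sampleVariants, tree = defaultPhylotree(),
                             mask = defaultHotspotMask()) {
  if (!nrow(tree@nodes)) stop("empty phylotree")
  sc <- .haplogroupScorer(tree, mask)
  sc(sampleVariants)
}

# Precompiled scorer: closures resolved to integer ids for speed.
.haplogroupScorer <- function(tree, mask = defaultHotspotMask()) {
  closure <- haplogroupClosure(tree)
  depth <- haplogroupDepths(tree)
  labels <- tree@nodes$haplogroup
  keep <- lengths(closure) > 0L
  universe <- unique(unlist(closure))
  cl_ids <- lapply(closure, function(v) match(v, universe))
  cl_len <- lengths(cl_ids)
  # lexicographic-then-depth ordering resolved once: higher depth first,
  # then label order, so the first argmax wins ties correctly
  ord <- order(-depth, labels)
  mask_chr <- as.character(mask)
  function(sampleVariants) {
    pos <- sub("_.*", "", sampleVariants)
    s <- sampleVariants[!(pos %in% mask_chr)]
    s_ids <- match(s, universe)
    s_ids <- unique(s_ids[!is.na(s_ids)])
    if (!length(s_ids))
      return(list(best = "unclassified", score = NA_real_,
                  runner_up = NA_character_, margin = NA_real_))
    inS <- logical(length(universe))
    inS[s_ids] <- TRUE
    inter <- vapply(cl_ids, function(ids) sum(inS[ids]), 0L)
    score <- unname(ifelse(keep, (inter / cl_len + inter / length(s_ids)) / 2,
                           0))
    so <- score[ord]
    i1 <- which.max(so)
    best <- labels[ord][i1]
    so[i1] <- -Inf
    i2 <- which.max(so)
    list(best = best, score = max(score),
         runner_up = labels[ord][i2],
         margin = max(score) - ifelse(is.finite(so[i2]), so[i2], 0))
  }
}

#' Assign haplogroups for every sample of a cohort
#'
#' Uses each sample's non-excluded variant calls.
#'
#' @param cohort a [MitoCohort-class].
#' @inheritParams assignHaplogroup
#' @return `data.frame`: `sample_id`, `group`, `haplogroup`, `score`,
#'   `runner_up`, `margin`.
#' @export
assignHaplogroups <- function(cohort, tree = defaultPhylotree(),
                              mask = defaultHotspotMask()) {
  cl <- calls(cohort)
  cl <- cl[cl$state != "excluded", , drop = FALSE]
  sm <- sampleGroups(cohort)
  sc <- .haplogroupScorer(tree, mask)
  by_sample <- split(cl$variant, factor(cl$sample_id, levels = sm$sample_id))
  res <- lapply(sm$sample_id, function(s) sc(by_sample[[s]]))
  data.frame(
    sample_id = sm$sample_id, group = sm$group,
    haplogroup = vapply(res, `[[`, "", "best"),
    score = vapply(res, `[[`, 0, "score"),
    runner_up = vapply(res, function(r) r$runner_up %||% NA_character_, ""),
    margin = vapply(res, `[[`, 0, "margin"),
    stringsAsFactors = FALSE)
}

#' Pool haplogroup assignments into major groups
#'
#' Truncates each assigned label to the longest matching major-label
#' prefix (e.g. `D4b2` pools as `D4`, `F1a` as `F`); labels matching none
#' pool as `"Others"`.  Returns contingency-ready per-group counts.
#'
#' @param assignments `data.frame` from [assignHaplogroups()] (needs
#'   `haplogroup` and `group` columns), or a character vector of labels.
#' @param majorLabels major haplogroup labels (default: the nine groups
#'   A, B, D4, D5, F, G, M7, R, Z).
#' @return `data.frame`: `haplogroup`, `cases`, `controls` (one row per
#'   major label plus `"Others"`).
#' @export
poolHaplogroups <- function(assignments,
                            majorLabels = c("A", "B", "D4", "D5", "F", "G",
                                            "M7", "R", "Z")) {
  if (is.character(assignments))
    assignments <- data.frame(haplogroup = assignments,
                              group = rep("case", length(assignments)),
                              stringsAsFactors = FALSE)
  lab <- assignments$haplogroup
  pooled <- vapply(lab, function(h) {
    hits <- majorLabels[startsWith(h, majorLabels)]
    if (!length(hits)) "Others" else hits[which.max(nchar(hits))]
  }, "")
  lev <- c(majorLabels, "Others")
  tab <- table(factor(pooled, levels = lev),
               factor(assignments$group, levels = c("case", "control")))
  data.frame(haplogroup = lev,
             cases = as.integer(tab[, "case"]),
             controls = as.integer(tab[, "control"]),
             stringsAsFactors = FALSE)
}
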