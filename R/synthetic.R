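#' Default per-group haplogroup frequencies
#'
#' Leaf-haplogroup sampling frequencies for the synthetic cohort, chosen
#' so that pooling to the nine major groups reproduces the study-scale
#' case/control proportions (e.g. D4 in 14/146 cases vs 23/120 controls,
#' designed odds ratio 0.447).
#'
#' @return list with probability vectors `cases` and `controls` named by
#'   leaf haplogroups of the packaged phylotree.
#' @export
defaultHaplogroupFrequencies <- function() {
  cases <- c(A15 = 14, B4a = 13, B5 = 12, D4a = 7, D4b = 7, D5a = 7,
             F1 = 17, F2 = 12, R11 = 14, G2 = 12, M7a = 8, M7b = 7,
             Z3 = 3, N9a = 5, Y1 = 4, M10 = 4)
  controls <- c(A15 = 5, B4a = 8, B5 = 8, D4a = 12, D4b = 11, D5a = 2,
                F1 = 12, F2 = 10, R11 = 16, G2 = 6, M7a = 5, M7b = 5,
                Z3 = 7, N9a = 5, Y1 = 4, M10 = 4)
  list(cases = cases / sum(cases), controls = controls / sum(controls))
}

#' Design of a synthetic case-control cohort
#'
#' Collects every tunable of the generator.  Defaults emulate the study
#' conditions: 146 cases vs 120 controls, haplogroup frequencies at the
#' study's per-group proportions, Poisson(5) private variants per
#' individual of which 60% are heteroplasmic with fractions uniform on
#' the observable band (0.01, 0.98), read depths around 500x, and a
#' symmetric per-read miscall rate of 0.001.  Private indels are more
#' frequent among heteroplasmic than homoplasmic private variants
#' (0.15 vs 0.02), emulating the indel-heteroplasmy enrichment seen in
#' real cohorts.
#'
#' @param nCases,nControls group sizes.
#' @param haplogroupFreqCases,haplogroupFreqControls named probability
#'   vectors over haplogroup labels (must sum to 1 within 1e-9).
#' @param privateVariantRate Poisson mean of private variants per
#'   individual.
#' @param hetProbability probability that a private variant is
#'   heteroplasmic.
#' @param hetFractionLaw function of `n` drawing true heteroplasmy
#'   fractions in (0.01, 0.98).
#' @param depthLaw function of `n` drawing positive integer read depths
#'   (mean >= 50).
#' @param errorRate per-read miscall probability (< 0.01).
#' @param indelFractionHet,indelFractionHom probability that a private
#'   heteroplasmic (resp. homoplasmic) variant is an indel.
#' @param seed integer seed driving all draws through one generator.
#' @return list of class `CohortDesign`.
#' @export
cohortDesign <- function(nCases = 146L, nControls = 120L,
                         haplogroupFreqCases = defaultHaplogroupFrequencies()$cases,
                         haplogroupFreqControls = defaultHaplogroupFrequencies()$controls,
                         privateVariantRate = 5,
                         hetProbability = 0.6,
                         hetFractionLaw = function(n) runif(n, 0.01, 0.98),
                         depthLaw = function(n) 1L + rnbinom(n, mu = 499, size = 10),
                         errorRate = 0.001,
                         indelFractionHet = 0.15,
                         indelFractionHom = 0.02,
                         seed = 1L) {
  stopifnot(abs(sum(haplogroupFreqCases) - 1) < 1e-9,
            abs(sum(haplogroupFreqControls) - 1) < 1e-9,
            hetProbability >= 0, hetProbability <= 1,
            errorRate < 0.01, errorRate >= 0,
            nCases >= 0, nControls >= 0)
  structure(list(
    nCases = as.integer(nCases), nControls = as.integer(nControls),
    haplogroupFreqCases = haplogroupFreqCases,
    haplogroupFreqControls = haplogroupFreqControls,
    privateVariantRate = privateVariantRate,
    hetProbability = hetProbability,
    hetFractionLaw = hetFractionLaw, depthLaw = depthLaw,
    errorRate = errorRate,
    indelFractionHet = indelFractionHet,
    indelFractionHom = indelFractionHom,
    seed = as.integer(seed)), class = "CohortDesign")
}

#' Simulate a case-control cohort
#'
#' For each sample: a haplogroup is drawn from its group's frequency
#' vector; the defining-variant closure of that haplogroup (all ancestors
#' included) is emitted as homoplasmic (true HF 1); private variants are
#' drawn Poisson at uniform random non-defining positions, heteroplasmic
#' with probability `hetProbability` (true HF from `hetFractionLaw`,
#' otherwise 1).  Each emitted call gets a depth from `depthLaw` and alt
#' reads Binomial(depth, f') with `f' = f(1-e) + (1-f)e` under the
#' symmetric per-read miscall rate `e`.  Fully reproducible given
#' `design$seed`.
#'
#' @param design a [cohortDesign()].
#' @param tree a [Phylotree-class]; all haplogroup labels of the design
#'   must exist in it.
#' @param refSeq reference sequence for private-variant alleles.
#' @return a [MitoCohort-class]; the truth tables (per-sample haplogroup,
#'   per-call true HF) are in `cohortTruth()`.
#' @export
simulateCohort <- function(design, tree = defaultPhylotree(),
                           refSeq = defaultMitoReference()) {
  stopifnot(inherits(design, "CohortDesign"))
  labels <- tree@nodes$haplogroup
  bad <- setdiff(c(names(design$haplogroupFreqCases),
                   names(design$haplogroupFreqControls)), labels)
  if (length(bad))
    stop("haplogroup label(s) not in the phylotree: ",
         paste(bad, collapse = ", "))
  set.seed(design$seed)
  closure <- haplogroupClosure(tree)
  tree_pos <- unique(as.integer(sub("_.*", "",
                                    unique(unlist(closure)))))
  L <- nchar(refSeq)
  bases <- c("A", "C", "G", "T")
  seq_chars <- strsplit(refSeq, "")[[1L]]
  free_pos <- setdiff(which(seq_chars %in% bases),
                      c(tree_pos, defaultHotspotMask()))
  n <- design$nCases + design$nControls
  groups <- rep(c("case", "control"), c(design$nCases, design$nControls))
  sample_id <- sprintf("S%03d", seq_len(n))
  hap <- character(n)
  if (design$nCases > 0)
    hap[groups == "case"] <- sample(names(design$haplogroupFreqCases),
                                    design$nCases, replace = TRUE,
                                    prob = design$haplogroupFreqCases)
  if (design$nControls > 0)
    hap[groups == "control"] <- sample(names(design$haplogroupFreqControls),
                                       design$nControls, replace = TRUE,
                                       prob = design$haplogroupFreqControls)

  # haplogroup-defining calls (homoplasmic truth)
  def_vars <- closure[hap]
  def_n <- lengths(def_vars)
  def <- data.frame(sample_id = rep(sample_id, def_n),
                    variant = unlist(def_vars, use.names = FALSE),
                    true_hf = 1, stringsAsFactors = FALSE)

  # private variants
  npriv <- rpois(n, design$privateVariantRate)
  tot <- sum(npriv)
  priv <- NULL
  if (tot > 0) {
    owner <- rep(sample_id, npriv)
    het <- runif(tot) < design$hetProbability
    true_hf <- ifelse(het, design$hetFractionLaw(tot), 1)
    is_indel <- runif(tot) < ifelse(het, design$indelFractionHet,
                                    design$indelFractionHom)
    pos <- sample(free_pos, tot, replace = TRUE)
    ref1 <- seq_chars[pos]
    transition <- c(A = "G", G = "A", C = "T", T = "C")
    tv <- vapply(ref1, function(b) sample(setdiff(bases, c(b, transition[[b]])), 1L), "")
    alt1 <- ifelse(runif(tot) < 0.7, transition[ref1], tv)
    ins <- runif(tot) < 0.5  # indels: half insertions, half deletions
    ref <- ifelse(is_indel & !ins & pos < L,
                  paste0(ref1, seq_chars[pmin(pos + 1L, L)]), ref1)
    alt <- ifelse(is_indel,
                  ifelse(ins, paste0(ref1, sample(bases, tot, replace = TRUE)),
                         ref1),
                  alt1)
    keep <- ref != alt
    priv <- data.frame(sample_id = owner,
                       variant = variantLabel(pos, ref, alt),
                       true_hf = true_hf,
                       stringsAsFactors = FALSE)[keep, , drop = FALSE]
    # a sample carries each variant at most once
    priv <- priv[!duplicated(priv[c("sample_id", "variant")]), , drop = FALSE]
    priv <- priv[!paste(priv$sample_id, priv$variant) %in%
                   paste(def$sample_id, def$variant), , drop = FALSE]
  }
  truth_calls <- rbind(def, priv)
  m <- nrow(truth_calls)
  depth <- design$depthLaw(m)
  stopifnot(all(depth >= 1))
  p <- truth_calls$true_hf * (1 - design$errorRate) +
    (1 - truth_calls$true_hf) * design$errorRate
  alt_reads <- rbinom(m, depth, p)
  calls <- data.frame(sample_id = truth_calls$sample_id,
                      variant = truth_calls$variant,
                      alt_reads = alt_reads,
                      total_reads = as.integer(depth),
                      stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sample_id, group = groups,
                        stringsAsFactors = FALSE)
  truth <- list(samples = data.frame(sample_id = sample_id, group = groups,
                                     true_haplogroup = hap,
                                     stringsAsFactors = FALSE),
                calls = truth_calls)
  makeCohort(calls, samples, metadata = list(truth = truth, design = design))
}

#' Write simulation truth tables
#'
#' One row per simulated call: the sample's group and true haplogroup and
#' the call's true heteroplasmy fraction, for parameter-recovery checks.
#' A cohort without calls yields a header-only file.
#'
#' @param cohort a simulated [MitoCohort-class].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeTruth <- function(cohort, path) {
  tr <- cohortTruth(cohort)
  if (is.null(tr)) stop("cohort carries no simulation truth")
  d <- merge(tr$calls, tr$samples, by = "sample_id", sort = FALSE)
  d <- d[c("sample_id", "group", "true_haplogroup", "variant", "true_hf")]
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTruth
#' @details `writeSampleTable()` writes the sample metadata TSV
#'   (`sample_id`, `group`).
#' @export
writeSampleTable <- function(cohort, path) {
  utils::write.table(sampleGroups(cohort), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
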