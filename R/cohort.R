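#' Heteroplasmy fraction from read counts
#'
#' HF is the fraction of reads supporting the variant allele at a site:
#' `alt_reads / total_reads`.
#'
#' @param altReads,totalReads non-negative integer vectors.
#' @return numeric vector of fractions.
#' @examples
#' computeHF(50, 100)  # 0.5
#' @export
computeHF <- function(altReads, totalReads) {
  if (any(totalReads <= 0L))
    stop("total_reads must be positive to define a heteroplasmy fraction")
  if (any(altReads < 0L) || any(altReads > totalReads))
    stop("alt_reads must lie in [0, total_reads]")
  altReads / totalReads
}

#' Classify a heteroplasmy fraction
#'
#' Variants with HF below 1% are excluded (likely sequencing error);
#' 1% <= HF < 98% is heteroplasmic; HF >= 98% is homoplasmic.
#'
#' @param hf numeric vector of fractions in `[0, 1]`.
#' @return character vector in
#'   `{"excluded","heteroplasmic","homoplasmic"}`.
#' @examples
#' classifyState(c(0.005, 0.01, 0.5, 0.98))
#' @export
classifyState <- function(hf) {
  stopifnot(all(hf >= 0 & hf <= 1))
  ifelse(hf < 0.01, "excluded",
         ifelse(hf < 0.98, "heteroplasmic", "homoplasmic"))
}

#' Bin a population allele frequency
#'
#' Common: AF >= 5%; low-frequency: 0.5% <= AF < 5%; rare: AF < 0.5%.
#'
#' @param af numeric vector of fractions in `[0, 1]`.
#' @return character vector in `{"common","low_frequency","rare"}`.
#' @export
binFrequency <- function(af) {
  stopifnot(all(af >= 0 & af <= 1))
  ifelse(af >= 0.05, "common",
         ifelse(af >= 0.005, "low_frequency", "rare"))
}

#' Construct a cohort from a calls table
#'
#' Computes HF and state for each call and validates the container.
#'
#' @param calls `data.frame` with columns `sample_id`, `variant` (or
#'   `position`/`ref`/`alt`), `alt_reads`, `total_reads`.
#' @param samples `data.frame` with columns `sample_id`, `group`.
#' @param metadata optional list (simulation truth etc.).
#' @return a [MitoCohort-class].
#' @export
makeCohort <- function(calls, samples, metadata = list()) {
  if (nrow(calls)) {
    if (!"variant" %in% names(calls))
      calls$variant <- variantLabel(calls$position, calls$ref, calls$alt)
    if (!all(c("position", "ref", "alt") %in% names(calls))) {
      p <- parseVariantLabel(calls$variant)
      calls$position <- p$position; calls$ref <- p$ref; calls$alt <- p$alt
    }
    calls$hf <- computeHF(calls$alt_reads, calls$total_reads)
    calls$state <- classifyState(calls$hf)
  } else {
    calls <- data.frame(sample_id = character(0), variant = character(0),
                        position = integer(0), ref = character(0),
                        alt = character(0), alt_reads = integer(0),
                        total_reads = integer(0), hf = numeric(0),
                        state = character(0), stringsAsFactors = FALSE)
  }
  new("MitoCohort", calls = calls, samples = samples, metadata = metadata)
}

#' Per-variant cohort summaries
#'
#' Collapses the cohort's calls to one row per variant: carrier counts by
#' group, the state profile (`heteroplasmic_only`, `homoplasmic_only` or
#' `both`), the control carrier frequency, whether the variant is known to
#' the annotation table (absent means novel), and the [binFrequency()] bin
#' of its known allele frequency (novel variants bin as rare).  Calls in
#' the `excluded` state (HF < 1%) are dropped first; the number dropped is
#' attached as attribute `n_excluded_calls`, and variants with no carrier
#' left are dropped with a message.
#'
#' @param cohort a [MitoCohort-class].
#' @param annotation optional `data.frame` with columns `variant` (or
#'   `pos`,`ref`,`alt`) and optionally `known_af`, `disease_link`.
#' @return `data.frame` with one row per retained variant.
#' @export
summarizeVariants <- function(cohort, annotation = NULL) {
  cl <- calls(cohort)
  sm <- sampleGroups(cohort)
  n_controls <- sum(sm$group == "control")
  n_cases <- sum(sm$group == "case")
  excluded <- cl$state == "excluded"
  dropped_variants <- setdiff(unique(cl$variant[excluded]),
                              unique(cl$variant[!excluded]))
  if (length(dropped_variants))
    message(length(dropped_variants),
            " variant(s) dropped entirely (all calls below the 1% HF floor)")
  cl <- cl[!excluded, , drop = FALSE]
  grp <- setNames(sm$group, sm$sample_id)
  if (!is.null(annotation)) {
    if (!"variant" %in% names(annotation))
      annotation$variant <- variantLabel(annotation$pos, annotation$ref,
                                         annotation$alt)
  }
  vs <- split(cl, cl$variant)
  rows <- lapply(vs, function(d) {
    g <- grp[d$sample_id]
    het <- any(d$state == "heteroplasmic")
    hom <- any(d$state == "homoplasmic")
    known <- !is.null(annotation) && d$variant[1L] %in% annotation$variant
    kaf <- if (known && "known_af" %in% names(annotation))
      annotation$known_af[match(d$variant[1L], annotation$variant)] else 0
    data.frame(
      variant = d$variant[1L], position = d$position[1L], ref = d$ref[1L],
      alt = d$alt[1L],
      var_class = .varClass(d$ref[1L], d$alt[1L]),
      carriers_cases = sum(g == "case"),
      carriers_controls = sum(g == "control"),
      state_profile = if (het && hom) "both"
                      else if (het) "heteroplasmic_only" else "homoplasmic_only",
      control_freq = if (n_controls > 0) sum(g == "control") / n_controls else NA_real_,
      known = known,
      freq_bin = binFrequency(ifelse(is.na(kaf), 0, kaf)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(variant = character(0), position = integer(0),
                      ref = character(0), alt = character(0),
                      var_class = character(0), carriers_cases = integer(0),
                      carriers_controls = integer(0),
                      state_profile = character(0), control_freq = numeric(0),
                      known = logical(0), freq_bin = character(0))
  out <- out[order(out$position, out$variant), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded_calls") <- sum(excluded)
  attr(out, "n_cases") <- n_cases
  attr(out, "n_controls") <- n_controls
  out
}

## ---- VCF input/output -------------------------------------------------------

#' Write a cohort as a multi-sample VCF
#'
#' Emits a plain-text VCF 4.2 with haploid genotypes and per-sample
#' `GT:AD:DP` fields.  Non-carrier samples are written as missing (`.`)
#' rather than reference genotypes, so the carrier set round-trips exactly.
#' Output is byte-deterministic for a given cohort (no timestamps).
#'
#' @param cohort a [MitoCohort-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCohortVCF <- function(cohort, path) {
  cl <- calls(cohort)
  sm <- sampleGroups(cohort)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=mitocase",
    "##contig=<ID=chrM,length=16569>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Read depth per allele\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sm$sample_id), collapse = "\t"))
  if (!nrow(cl)) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  key <- unique(cl[order(cl$position, cl$ref, cl$alt),
                   c("variant", "position", "ref", "alt")])
  cl_idx <- split(seq_len(nrow(cl)), cl$variant)
  lines <- vapply(seq_len(nrow(key)), function(i) {
    idx <- cl_idx[[key$variant[i]]]
    d <- cl[idx, ]
    fmt <- setNames(rep(".", nrow(sm)), sm$sample_id)
    fmt[d$sample_id] <- sprintf("1:%d,%d:%d", d$total_reads - d$alt_reads,
                                d$alt_reads, d$total_reads)
    paste(c("chrM", key$position[i], ".", key$ref[i], key$alt[i], ".",
            "PASS", ".", "GT:AD:DP", unname(fmt)), collapse = "\t")
  }, "")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a multi-sample VCF into a cohort
#'
#' Parses per-sample `AD`/`DP` FORMAT fields with vcfR, splits
#' multi-allelic records into biallelic calls (HF is per alternate
#' allele), computes HF and state, and pairs the calls with the given
#' sample-group table.  A sample carries a variant when its genotype is
#' non-missing and includes the alternate allele.
#'
#' @param path VCF file (plain text or gzipped).
#' @param samples `data.frame` with columns `sample_id`, `group`; defaults
#'   to all samples in the VCF as controls.
#' @return a [MitoCohort-class].
#' @export
readCohortVCF <- function(path, samples = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- vcfR::extract.gt(v, element = "AD")
  sample_ids <- colnames(gt)
  if (is.null(samples))
    samples <- data.frame(sample_id = sample_ids, group = "control",
                          stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    for (s in sample_ids) {
      g <- gt[i, s]
      if (is.na(g) || g %in% c(".", "./.", ".|.")) next
      alleles <- suppressWarnings(
        as.integer(strsplit(g, "[/|]")[[1L]]))
      adv <- suppressWarnings(
        as.integer(strsplit(ad[i, s], ",", fixed = TRUE)[[1L]]))
      for (k in seq_along(alts)) {
        if (!(k %in% alleles)) next
        alt_reads <- if (length(adv) >= k + 1L) adv[k + 1L] else NA_integer_
        total <- sum(adv, na.rm = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = s,
          position = as.integer(fix[i, "POS"]),
          ref = fix[i, "REF"], alt = alts[k],
          alt_reads = alt_reads, total_reads = total,
          stringsAsFactors = FALSE)
      }
    }
  }
  calls <- if (length(rows)) do.call(rbind, rows)
           else data.frame(sample_id = character(0), position = integer(0),
                           ref = character(0), alt = character(0),
                           alt_reads = integer(0), total_reads = integer(0))
  makeCohort(calls, samples, metadata = list(source = path))
}

#' Write per-variant and per-sample tables
#'
#' `writeVariantSummary()` and `writeSampleCalls()` export the standard
#' TSV reports.
#'
#' @param x a summary `data.frame` ([summarizeVariants()]) or a
#'   [MitoCohort-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeVariantSummary <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeVariantSummary
#' @export
writeSampleCalls <- function(x, path) {
  stopifnot(is(x, "MitoCohort"))
  utils::write.table(calls(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
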