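#' 2x2 contingency table
#'
#' Convention used throughout: `a` exposed cases, `b` unexposed cases,
#' `c` exposed controls, `d` unexposed controls.
#'
#' @param a,b,c,d non-negative cell counts.
#' @return named list of class `ContingencyTable`.
#' @export
contingencyTable <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  structure(as.list(cells), class = "ContingencyTable")
}

.asTable <- function(t) {
  if (inherits(t, "ContingencyTable")) t
  else if (is.matrix(t)) contingencyTable(t[1, 1], t[1, 2], t[2, 1], t[2, 2])
  else do.call(contingencyTable, as.list(t))
}

.asMatrix <- function(t) matrix(c(t$a, t$b, t$c, t$d), 2, byrow = TRUE,
                                dimnames = list(c("case", "control"),
                                                c("exposed", "unexposed")))

#' Odds ratio with Woolf 95% confidence interval
#'
#' `OR = ad / bc`; the Woolf interval is
#' `exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`.  When any cell is
#' zero the Haldane-Anscombe correction adds 0.5 to every cell first
#' (`correction_applied` records this).  Fisher exact, Pearson chi-square
#' (no Yates) and Wald logistic p-values are reported side by side; the
#' Wald p falls back to `NA` when the table is separated.
#'
#' @param t a [contingencyTable()], 2x2 matrix, or numeric vector
#'   `c(a, b, c, d)`.
#' @param conf confidence level (default 0.95).
#' @return list of class `ContingencyResult`: `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_fisher`, `p_chi2`, `p_wald`, `correction_applied`,
#'   plus the (uncorrected) cells.
#' @examples
#' r <- oddsRatio(c(14, 132, 23, 97))  # haplogroup D4, 146 cases/120 controls
#' round(c(r$odds_ratio, r$ci_low, r$ci_high), 3)  # 0.447 0.219 0.914
#' @export
oddsRatio <- function(t, conf = 0.95) {
  t <- .asTable(t)
  cells <- c(t$a, t$b, t$c, t$d)
  if (all(cells == 0)) stop("degenerate all-zero table")
  correction <- any(cells == 0)
  w <- if (correction) cells + 0.5 else cells
  or <- (w[1] * w[4]) / (w[2] * w[3])
  z <- qnorm(1 - (1 - conf) / 2)
  se <- sqrt(sum(1 / w))
  chi <- chiSquare(t)
  wald <- tryCatch(
    if (correction) NA_real_
    else logisticFit(rep(c(1, 0, 1, 0), cells),
                     rep(c(1, 1, 0, 0), cells))$p_wald,
    error = function(e) NA_real_, warning = function(w) NA_real_)
  structure(list(
    odds_ratio = or,
    ci_low = exp(log(or) - z * se),
    ci_high = exp(log(or) + z * se),
    p_fisher = fisherExact(t),
    p_chi2 = chi$p,
    p_wald = wald,
    correction_applied = correction,
    a = t$a, b = t$b, c = t$c, d = t$d), class = "ContingencyResult")
}

#' @method print ContingencyResult
#' @export
print.ContingencyResult <- function(x, ...) {
  cat(sprintf("OR %.3f (95%% CI %.3f-%.3f)%s\n", x$odds_ratio, x$ci_low,
              x$ci_high, if (x$correction_applied) " [Haldane 0.5]" else ""))
  cat(sprintf("  p: Fisher %.4g, chi-square %.4g, Wald %.4g\n",
              x$p_fisher, x$p_chi2, x$p_wald))
  invisible(x)
}

#' Two-sided Fisher exact test of a 2x2 table
#'
#' Point-probability method: the p-value sums hypergeometric point
#' probabilities no larger than that of the observed table (the
#' convention of `stats::fisher.test`, stated here for reproducibility).
#' Degenerate tables (a zero margin) give p = 1.
#'
#' @inheritParams oddsRatio
#' @return two-sided p-value.
#' @export
fisherExact <- function(t) {
  t <- .asTable(t)
  m <- .asMatrix(t)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
  stats::fisher.test(m)$p.value
}

#' Pearson chi-square test
#'
#' For a 2x2 table the statistic is `n(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`;
#' the method generalizes to r x c tables.  A table with a zero margin is
#' flagged degenerate (`NA` statistic) rather than erroring.
#'
#' @param t a 2x2 specification as in [oddsRatio()], or an r x c matrix.
#' @param yates apply Yates continuity correction (2x2 only).
#' @return list `statistic`, `df`, `p`, `degenerate`.
#' @export
chiSquare <- function(t, yates = FALSE) {
  m <- if (is.matrix(t) && !all(dim(t) == c(2L, 2L))) t
       else .asMatrix(.asTable(t))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    return(list(statistic = NA_real_, df = NA_integer_, p = NA_real_,
                degenerate = TRUE))
  r <- suppressWarnings(stats::chisq.test(m, correct = yates))
  list(statistic = unname(r$statistic), df = unname(r$parameter),
       p = r$p.value, degenerate = FALSE)
}

#' Single-covariate logistic regression
#'
#' Maximum-likelihood fit of `outcome ~ exposure` by iteratively
#' reweighted least squares (via `stats::glm`, convergence tightened to
#' 1e-12).  With a binary exposure the fitted odds ratio equals the 2x2
#' cross-product ratio.  Complete separation (a zero cell in the implied
#' table) has no finite MLE: the fit falls back to the Haldane-corrected
#' contingency odds ratio with a warning and `separated = TRUE`.
#'
#' @param exposure numeric covariate vector (binary or continuous).
#' @param outcome binary 0/1 vector.
#' @return list `beta`, `se`, `p_wald`, `odds_ratio`, `separated`.
#' @export
logisticFit <- function(exposure, outcome) {
  stopifnot(length(exposure) == length(outcome),
            all(outcome %in% c(0, 1)))
  if (length(unique(outcome)) < 2L) stop("outcome has a single class")
  if (length(unique(exposure)) < 2L) stop("exposure is constant")
  binary <- all(exposure %in% c(0, 1))
  if (binary) {
    a <- sum(exposure == 1 & outcome == 1); b <- sum(exposure == 0 & outcome == 1)
    c_ <- sum(exposure == 1 & outcome == 0); d <- sum(exposure == 0 & outcome == 0)
    if (any(c(a, b, c_, d) == 0)) {
      warning("separation: falling back to the Haldane-corrected contingency OR")
      w <- c(a, b, c_, d) + 0.5
      or <- (w[1] * w[4]) / (w[2] * w[3])
      se <- sqrt(sum(1 / w))
      return(list(beta = log(or), se = se,
                  p_wald = 2 * stats::pnorm(-abs(log(or) / se)),
                  odds_ratio = or, separated = TRUE))
    }
  }
  fit <- glm(outcome ~ exposure, family = binomial(),
             control = glm.control(epsilon = 1e-12, maxit = 100))
  s <- summary(fit)$coefficients
  list(beta = s["exposure", "Estimate"], se = s["exposure", "Std. Error"],
       p_wald = s["exposure", "Pr(>|z|)"],
       odds_ratio = exp(s["exposure", "Estimate"]), separated = FALSE)
}

#' Mann-Whitney U test
#'
#' U from rank sums with midranks for ties; the p-value is exact (by
#' enumeration of rank assignments) when `n_x + n_y <= 20` and there are
#' no ties, otherwise a normal approximation with tie and continuity
#' correction is used.  Two-sided.
#'
#' @param x,y numeric samples.
#' @return list `U` (statistic of `x`), `p`, `exact`.
#' @export
mannWhitney <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && (length(x) + length(y)) <= 20L
  r <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE,
                alternative = "two.sided"))
  list(U = unname(r$statistic), p = r$p.value, exact = exact)
}

#' MAF retention rule for SNP association
#'
#' A SNP is excluded only when its minor allele frequency is below the
#' floor in *both* groups; at or above the floor in either group retains
#' it (the floor is strict: exactly 5% is retained).
#'
#' @param mafCases,mafControls minor allele frequencies per group.
#' @param floor MAF floor (default 0.05).
#' @return logical vector: `TRUE` = retained.
#' @export
mafFilter <- function(mafCases, mafControls, floor = 0.05) {
  !(mafCases < floor & mafControls < floor)
}

#' Per-SNP case-control association
#'
#' Builds the carrier/non-carrier 2x2 per variant, applies the MAF floor
#' (carrier frequency, folded to the minor allele), and tests each
#' retained SNP by logistic regression (equivalently the contingency OR
#' for a binary covariate).  Raw and Benjamini-Hochberg adjusted p-values
#' are reported side by side; output is never gated on the adjusted ones.
#'
#' @param summaries output of [summarizeVariants()] (needs
#'   `carriers_cases`, `carriers_controls` and attributes `n_cases`,
#'   `n_controls`, or pass them explicitly).
#' @param nCases,nControls group sizes.
#' @param mafFloor MAF floor (default 0.05).
#' @param substitutionsOnly restrict to single-base substitutions
#'   (default TRUE, matching the SNP definition).
#' @return `data.frame`: one row per retained SNP with cells, OR, Woolf
#'   CI, `p_fisher`, `p_chi2`, `p_wald`, `p_bh` (BH-adjusted Wald).
#' @export
snpAssociation <- function(summaries,
                           nCases = attr(summaries, "n_cases"),
                           nControls = attr(summaries, "n_controls"),
                           mafFloor = 0.05, substitutionsOnly = TRUE) {
  stopifnot(!is.null(nCases), !is.null(nControls))
  d <- summaries
  if (substitutionsOnly && "var_class" %in% names(d))
    d <- d[d$var_class == "substitution", , drop = FALSE]
  f_cases <- d$carriers_cases / nCases
  f_controls <- d$carriers_controls / nControls
  maf_cases <- pmin(f_cases, 1 - f_cases)
  maf_controls <- pmin(f_controls, 1 - f_controls)
  keep <- mafFilter(maf_cases, maf_controls, mafFloor)
  d <- d[keep, , drop = FALSE]
  if (!nrow(d))
    return(data.frame(variant = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0), odds_ratio = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      p_fisher = numeric(0), p_chi2 = numeric(0),
                      p_wald = numeric(0), p_bh = numeric(0)))
  res <- lapply(seq_len(nrow(d)), function(i) {
    a <- d$carriers_cases[i]; b <- nCases - a
    c_ <- d$carriers_controls[i]; dd <- nControls - c_
    r <- oddsRatio(c(a, b, c_, dd))
    data.frame(variant = d$variant[i], a = a, b = b, c = c_, d = dd,
               odds_ratio = r$odds_ratio, ci_low = r$ci_low,
               ci_high = r$ci_high, p_fisher = r$p_fisher,
               p_chi2 = r$p_chi2, p_wald = r$p_wald,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  # BH on the Wald column; separated tables (NA Wald) fall back to Fisher
  p_for_adjust <- ifelse(is.na(out$p_wald), out$p_fisher, out$p_wald)
  out$p_bh <- p.adjust(p_for_adjust, method = "BH")
  rownames(out) <- NULL
  out
}

#' Haplogroup vs all-others association
#'
#' Table-style analysis: each major haplogroup is tested against all
#' remaining haplogroups as the reference group.
#'
#' @param pooled output of [poolHaplogroups()].
#' @return `data.frame` with one row per haplogroup: cells, OR, CI and
#'   the three p-values, plus BH-adjusted Wald p.
#' @export
haplogroupAssociation <- function(pooled) {
  n_cases <- sum(pooled$cases); n_controls <- sum(pooled$controls)
  res <- lapply(seq_len(nrow(pooled)), function(i) {
    a <- pooled$cases[i]; b <- n_cases - a
    c_ <- pooled$controls[i]; d <- n_controls - c_
    r <- oddsRatio(c(a, b, c_, d))
    data.frame(haplogroup = pooled$haplogroup[i],
               cases = a, controls = c_,
               odds_ratio = r$odds_ratio, ci_low = r$ci_low,
               ci_high = r$ci_high, p_fisher = r$p_fisher,
               p_chi2 = r$p_chi2, p_wald = r$p_wald,
               correction_applied = r$correction_applied,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  p_for_adjust <- ifelse(is.na(out$p_wald), out$p_fisher, out$p_wald)
  out$p_bh <- p.adjust(p_for_adjust, method = "BH")
  out
}

#' Per-region mutational burden comparison
#'
#' Counts each sample's non-excluded calls per genomic region (plus the
#' total and a protein-coding aggregate), summarizes group means and SDs,
#' and compares groups per region by the Mann-Whitney U test.
#'
#' @param cohort a [MitoCohort-class].
#' @param gm a [MitoGenomeMap-class].
#' @param heteroplasmicOnly restrict to heteroplasmic calls.
#' @return list with `per_sample` (long `data.frame` of counts) and
#'   `summary` (per region: group means/SDs, U, p).
#' @export
burdenByRegion <- function(cohort, gm = defaultGenomeMap(),
                           heteroplasmicOnly = FALSE) {
  cl <- calls(cohort)
  sm <- sampleGroups(cohort)
  cl <- cl[cl$state != "excluded", , drop = FALSE]
  if (heteroplasmicOnly)
    cl <- cl[cl$state == "heteroplasmic", , drop = FALSE]
  cl$region <- if (nrow(cl)) assignRegion(cl$position, gm) else character(0)
  f <- features(gm)
  coding <- f$name[f$kind == "protein"]
  regions <- c(f$name, "intergenic")
  mat <- table(factor(cl$sample_id, levels = sm$sample_id),
               factor(cl$region, levels = regions))
  per_sample <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(per_sample) <- c("sample_id", "region", "count")
  extra <- data.frame(
    sample_id = rep(sm$sample_id, 2L),
    region = rep(c("total", "coding"), each = nrow(sm)),
    count = c(as.integer(rowSums(mat)),
              as.integer(rowSums(mat[, coding, drop = FALSE]))),
    stringsAsFactors = FALSE)
  per_sample <- rbind(per_sample, extra)
  per_sample$group <- sm$group[match(per_sample$sample_id, sm$sample_id)]
  summ <- lapply(split(per_sample, per_sample$region), function(d) {
    x <- d$count[d$group == "case"]; y <- d$count[d$group == "control"]
    mw <- if (length(x) && length(y) && (length(unique(c(x, y))) > 1L))
      mannWhitney(x, y) else list(U = NA_real_, p = 1)
    data.frame(region = d$region[1L],
               mean_cases = mean(x), sd_cases = sd(x),
               mean_controls = mean(y), sd_controls = sd(y),
               U = mw$U, p = mw$p, stringsAsFactors = FALSE)
  })
  summ <- do.call(rbind, c(summ, list(make.row.names = FALSE)))
  list(per_sample = per_sample, summary = summ)
}

#' Indel enrichment tests
#'
#' Builds (i) the 2x2 state x {indel, SNV} table over variants observed
#' only heteroplasmic vs only homoplasmic (variants seen in both states
#' are excluded from this contrast) and (ii) the region-category x
#' {indel, SNV} table over all retained variants, and tests (i) by
#' chi-square and Fisher exact and (ii) by chi-square.  Degenerate tables
#' (e.g. no indels at all) are flagged, not errored.
#'
#' @param summaries output of [summarizeVariants()].
#' @param gm a [MitoGenomeMap-class].
#' @return list with `state_table`, `p_chi2_state`, `p_fisher_state`,
#'   `region_table`, `p_chi2_region`, `degenerate`.
#' @export
indelEnrichment <- function(summaries, gm = defaultGenomeMap()) {
  is_indel <- summaries$var_class != "substitution"
  st <- summaries$state_profile
  keep <- st %in% c("heteroplasmic_only", "homoplasmic_only")
  state_table <- table(
    factor(st[keep], levels = c("heteroplasmic_only", "homoplasmic_only")),
    factor(ifelse(is_indel[keep], "indel", "SNV"), levels = c("indel", "SNV")))
  chi_state <- chiSquare(unclass(state_table))
  fisher_state <- if (chi_state$degenerate) NA_real_
                  else stats::fisher.test(state_table)$p.value
  f <- features(gm)
  region <- assignRegion(summaries$position, gm)
  kind <- ifelse(region == "intergenic", "noncoding",
                 f$kind[match(region, f$name)])
  kind[kind %in% c("control", "noncoding")] <- "noncoding"
  region_table <- table(factor(kind, levels = c("protein", "rRNA", "tRNA",
                                                "noncoding")),
                        factor(ifelse(is_indel, "indel", "SNV"),
                               levels = c("indel", "SNV")))
  region_table <- region_table[rowSums(region_table) > 0, , drop = FALSE]
  chi_region <- chiSquare(unclass(region_table))
  list(state_table = state_table,
       p_chi2_state = chi_state$p, p_fisher_state = fisher_state,
       region_table = region_table, p_chi2_region = chi_region$p,
       degenerate = chi_state$degenerate || chi_region$degenerate)
}
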