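#' Predictor tool registry
#'
#' The 13 protein-variant deleteriousness predictors consumed by the
#' consensus vote, with the score threshold and direction that convert a
#' raw score into a deleterious/benign verdict.  `direction = "higher"`
#' means scores above the threshold are deleterious (PolyPhen2, CADD, ...);
#' `"lower"` means scores below it are (SIFT, PROVEAN, FatHmm).  The
#' registry ships as an editable TSV; the package never runs the external
#' tools — their scores are inputs.
#'
#' @param path registry TSV (`tool`, `threshold`, `direction`); default:
#'   packaged registry.
#' @return `data.frame` with 13 rows.
#' @export
predictorRegistry <- function(path = .extdata("predictor_tools.tsv")) {
  reg <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("tool", "threshold", "direction") %in% names(reg)),
            all(reg$direction %in% c("higher", "lower")))
  reg
}

#' Verdict of one predictor score
#'
#' @param tool tool name (must be in the registry).
#' @param score numeric score (`NA` = tool produced no result).
#' @param registry see [predictorRegistry()].
#' @return `"deleterious"`, `"benign"` or `"missing"`.
#' @export
predictorVerdict <- function(tool, score, registry = predictorRegistry()) {
  i <- match(tool, registry$tool)
  if (any(is.na(i))) stop("unknown predictor tool: ",
                          paste(tool[is.na(i)], collapse = ", "))
  del <- ifelse(registry$direction[i] == "higher",
                score > registry$threshold[i], score < registry$threshold[i])
  ifelse(is.na(score), "missing", ifelse(del, "deleterious", "benign"))
}

#' Control-frequency filter
#'
#' A variant passes when its carrier frequency among healthy controls is
#' strictly below 1%; variants at or above the threshold are regarded as
#' polymorphisms.
#'
#' @param controlFreq numeric vector of control carrier frequencies.
#' @return logical vector.
#' @export
frequencyFilter <- function(controlFreq) {
  stopifnot(all(is.na(controlFreq) | (controlFreq >= 0 & controlFreq <= 1)))
  !is.na(controlFreq) & controlFreq < 0.01
}

#' MitoTip quartile classification
#'
#' Raw MitoTip scores map to quartile classes: > 16.25 Likely Pathogenic
#' (LP); 12.66-16.25 Possibly Pathogenic (PP); 8.44-12.66 Possibly Benign
#' (PB); < 8.44 Likely Benign (LB).  Boundary scores equal to 12.66 or
#' 8.44 take the higher class; 16.25 itself is PP since only the LP bound
#' is strict.  A missing score returns `"n/a"`.
#'
#' @param score numeric vector of raw MitoTip scores.
#' @return character vector in `{"LP","PP","PB","LB","n/a"}`.
#' @examples
#' mitotipClassify(c(17, 16.25, 12.66, 8.44, 5))
#' @export
mitotipClassify <- function(score) {
  ifelse(is.na(score), "n/a",
         ifelse(score > 16.25, "LP",
                ifelse(score >= 12.66, "PP",
                       ifelse(score >= 8.44, "PB", "LB"))))
}

#' Consensus vote over predictor calls
#'
#' Counts deleterious verdicts over the 13-tool registry; the variant is
#' called deleterious when more than six tools agree.  Missing verdicts
#' count as non-deleterious while the absolute more-than-six-of-13
#' threshold is kept.
#'
#' @param verdicts character vector of verdicts named by tool (values from
#'   [predictorVerdict()]), at most one per tool.
#' @param registry see [predictorRegistry()].
#' @return list with `votes` (integer) and `deleterious` (logical).
#' @export
consensusVote <- function(verdicts, registry = predictorRegistry()) {
  tools <- names(verdicts)
  if (is.null(tools)) stop("verdicts must be named by tool")
  if (anyDuplicated(tools))
    stop("duplicate predictor call for tool: ",
         paste(unique(tools[duplicated(tools)]), collapse = ", "))
  unknown <- setdiff(tools, registry$tool)
  if (length(unknown))
    stop("unknown predictor tool: ", paste(unknown, collapse = ", "))
  votes <- sum(verdicts == "deleterious", na.rm = TRUE)
  list(votes = as.integer(votes), deleterious = votes > 6L)
}

#' Variant prioritization cascade
#'
#' Applies the study's cascade to every variant: control-frequency filter,
#' then conservation filter, then the region-appropriate classifier —
#' MitoTip quartile class (LP/PP deleterious) for tRNA variants, the
#' 13-predictor consensus vote (> 6 of 13) for nonsynonymous protein
#' variants.  Synonymous protein variants and variants in other regions
#' are never prioritized.  Each variant gets a full audit trail: the stage
#' at which it left the cascade (`not_eligible`, `frequency`,
#' `conservation`, `classifier`, `no_data`) or `none` if prioritized.
#'
#' @param summaries `data.frame` with `variant` and either `control_freq`
#'   or `carriers_controls` + `n_controls` ([summarizeVariants()] output
#'   works directly).
#' @param effects `data.frame` with `variant`, `region`
#'   (`"protein"`/`"tRNA"`/... or a feature kind) and `coding_effect`.
#' @param ci `data.frame` with `variant`, `ci` (fraction; `NA` = no CI).
#' @param mitotipScores `data.frame` with `variant`, `score` (tRNA path).
#' @param predictorScores long `data.frame` with `variant`, `tool`,
#'   `score` (protein path); absent rows are missing results.
#' @param registry see [predictorRegistry()].
#' @param ciThreshold strict CI bound (default 0.75).
#' @return `data.frame`: one row per variant in `summaries` with columns
#'   `variant`, `pathway`, `passed_frequency`, `passed_conservation`,
#'   `mitotip_class`, `consensus_votes`, `final`
#'   (`deleterious_tRNA`/`deleterious_protein`/`not_prioritized`) and
#'   `stage_failed`.
#' @export
runCascade <- function(summaries, effects, ci, mitotipScores = NULL,
                       predictorScores = NULL,
                       registry = predictorRegistry(), ciThreshold = 0.75) {
  stopifnot("variant" %in% names(summaries))
  if (!"control_freq" %in% names(summaries)) {
    stopifnot(all(c("carriers_controls", "n_controls") %in% names(summaries)))
    summaries$control_freq <- summaries$carriers_controls / summaries$n_controls
  }
  n <- nrow(summaries)
  kind_col <- if ("region_kind" %in% names(effects)) "region_kind" else "region"
  eff_kind <- effects[[kind_col]][match(summaries$variant, effects$variant)]
  eff_ce <- effects$coding_effect[match(summaries$variant, effects$variant)]
  ci_val <- ci$ci[match(summaries$variant, ci$variant)]
  ci_seen <- summaries$variant %in% ci$variant
  mt <- if (!is.null(mitotipScores))
    mitotipScores$score[match(summaries$variant, mitotipScores$variant)]
    else rep(NA_real_, n)
  votes <- rep(NA_integer_, n)
  if (!is.null(predictorScores)) {
    sp <- split(predictorScores, predictorScores$variant)
    for (v in names(sp)) {
      i <- which(summaries$variant == v)
      if (!length(i)) next
      d <- sp[[v]]
      verd <- setNames(predictorVerdict(d$tool, d$score, registry), d$tool)
      votes[i] <- consensusVote(verd, registry)$votes
    }
  }
  out <- data.frame(
    variant = summaries$variant,
    pathway = ifelse(is.na(eff_kind), "unknown",
                     ifelse(eff_kind == "tRNA", "tRNA",
                            ifelse(eff_kind == "protein", "protein", "other"))),
    passed_frequency = NA, passed_conservation = NA,
    mitotip_class = "n/a", consensus_votes = NA_integer_,
    final = "not_prioritized", stage_failed = "none",
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    if (is.na(eff_kind[i])) { out$stage_failed[i] <- "no_data"; next }
    eligible <- (out$pathway[i] == "tRNA") ||
      (out$pathway[i] == "protein" && identical(eff_ce[i], "nonsynonymous"))
    if (!eligible) { out$stage_failed[i] <- "not_eligible"; next }
    pf <- frequencyFilter(summaries$control_freq[i])
    out$passed_frequency[i] <- pf
    if (!pf) { out$stage_failed[i] <- "frequency"; next }
    if (!ci_seen[i]) { out$stage_failed[i] <- "no_data"; next }
    pc <- !is.na(ci_val[i]) && ci_val[i] > ciThreshold
    out$passed_conservation[i] <- pc
    if (!pc) {
      out$stage_failed[i] <- if (is.na(ci_val[i])) "no_data" else "conservation"
      next
    }
    if (out$pathway[i] == "tRNA") {
      cls <- mitotipClassify(mt[i])
      out$mitotip_class[i] <- cls
      if (cls %in% c("LP", "PP")) {
        out$final[i] <- "deleterious_tRNA"
      } else {
        out$stage_failed[i] <- if (cls == "n/a") "no_data" else "classifier"
      }
    } else {
      if (is.na(votes[i])) { out$stage_failed[i] <- "no_data"; next }
      out$consensus_votes[i] <- votes[i]
      if (votes[i] > 6L) {
        out$final[i] <- "deleterious_protein"
      } else {
        out$stage_failed[i] <- "classifier"
      }
    }
  }
  out
}

#' Stage-by-stage survivor counts of a cascade report
#'
#' @param cascade output of [runCascade()].
#' @return `data.frame` with rows for the tRNA and protein pathways and
#'   columns `eligible`, `pass_frequency`, `pass_conservation`,
#'   `deleterious`.
#' @export
cascadeAudit <- function(cascade) {
  one <- function(pw, final_label) {
    d <- cascade[cascade$pathway == pw & cascade$stage_failed != "not_eligible", ]
    data.frame(
      pathway = pw,
      eligible = nrow(d),
      pass_frequency = sum(d$passed_frequency, na.rm = TRUE),
      pass_conservation = sum(d$passed_conservation, na.rm = TRUE),
      deleterious = sum(d$final == final_label),
      stringsAsFactors = FALSE)
  }
  rbind(one("tRNA", "deleterious_tRNA"), one("protein", "deleterious_protein"))
}
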