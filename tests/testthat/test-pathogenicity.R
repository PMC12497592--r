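test_that("MitoTip quartile classes respect the printed boundaries", {
  expect_equal(mitotipClassify(17.0), "LP")
  expect_equal(mitotipClassify(16.26), "LP")
  expect_equal(mitotipClassify(16.25), "PP")  # only the LP bound is strict
  expect_equal(mitotipClassify(12.66), "PP")  # boundary to the higher class
  expect_equal(mitotipClassify(12.65), "PB")
  expect_equal(mitotipClassify(8.44), "PB")   # boundary to the higher class
  expect_equal(mitotipClassify(8.43), "LB")
  expect_equal(mitotipClassify(5.0), "LB")
  expect_equal(mitotipClassify(NA), "n/a")
})

test_that("every finite score gets exactly one MitoTip class", {
  set.seed(8)
  scores <- c(runif(200, -5, 30), 16.25, 12.66, 8.44)
  cls <- mitotipClassify(scores)
  expect_true(all(cls %in% c("LP", "PP", "PB", "LB")))
})

test_that("consensus vote needs more than six of the 13 programs", {
  reg <- predictorRegistry()
  all13 <- setNames(rep("deleterious", 13), reg$tool)
  expect_equal(consensusVote(all13), list(votes = 13L, deleterious = TRUE))
  v7 <- setNames(c(rep("deleterious", 7), rep("benign", 6)), reg$tool)
  expect_equal(consensusVote(v7)$deleterious, TRUE)
  v6 <- setNames(c(rep("deleterious", 6), rep("benign", 7)), reg$tool)
  expect_equal(consensusVote(v6), list(votes = 6L, deleterious = FALSE))
  # missing verdicts count as non-deleterious against the absolute threshold
  v_part <- setNames(c(rep("deleterious", 6), "missing"), reg$tool[1:7])
  expect_false(consensusVote(v_part)$deleterious)
  expect_error(consensusVote(setNames(rep("deleterious", 2),
                                      rep(reg$tool[1], 2))), "duplicate")
  expect_error(consensusVote(c(SomethingElse = "deleterious")), "unknown")
})

test_that("predictor verdicts honor per-tool score directions", {
  reg <- predictorRegistry()
  expect_equal(nrow(reg), 13L)
  expect_equal(predictorVerdict("SIFT", 0.01), "deleterious")   # lower = worse
  expect_equal(predictorVerdict("SIFT", 0.2), "benign")
  expect_equal(predictorVerdict("PolyPhen2", 0.95), "deleterious")
  expect_equal(predictorVerdict("PolyPhen2", 0.1), "benign")
  expect_equal(predictorVerdict("CADD", NA), "missing")
})

test_that("the control-frequency gate is strict at 1%", {
  expect_true(frequencyFilter(0 / 120))
  expect_true(frequencyFilter(1 / 120))   # 0.83% passes
  expect_false(frequencyFilter(2 / 120))  # 1.67% is a polymorphism
  expect_false(frequencyFilter(0.01))
})

test_that("the cascade routes tRNA and protein variants through their gates", {
  summaries <- data.frame(
    variant = c("t1", "p1", "p2", "x1"),
    control_freq = c(0, 0.008, 0, 0),
    stringsAsFactors = FALSE)
  effects <- data.frame(
    variant = c("t1", "p1", "p2", "x1"),
    region = c("tRNA", "protein", "protein", "rRNA"),
    coding_effect = c("noncoding", "nonsynonymous", "synonymous", "noncoding"),
    stringsAsFactors = FALSE)
  ci <- data.frame(variant = c("t1", "p1", "p2", "x1"),
                   ci = c(0.9, 0.85, 0.9, 0.95))
  mt <- data.frame(variant = "t1", score = 13.0)  # PP
  reg <- predictorRegistry()
  pred <- data.frame(variant = "p1", tool = reg$tool,
                     score = ifelse(reg$direction == "higher",
                                    reg$threshold + 1, reg$threshold - 1))
  pred <- pred[1:10, ]  # 10 deleterious scores, 3 missing
  res <- runCascade(summaries, effects, ci, mt, pred)
  expect_equal(res$final[res$variant == "t1"], "deleterious_tRNA")
  expect_equal(res$mitotip_class[res$variant == "t1"], "PP")
  expect_equal(res$final[res$variant == "p1"], "deleterious_protein")
  expect_equal(res$consensus_votes[res$variant == "p1"], 10L)
  # synonymous protein and rRNA variants are never prioritized
  expect_equal(res$final[res$variant == "p2"], "not_prioritized")
  expect_equal(res$stage_failed[res$variant == "p2"], "not_eligible")
  expect_equal(res$stage_failed[res$variant == "x1"], "not_eligible")
})

test_that("missing inputs surface as no_data, not silent drops", {
  summaries <- data.frame(variant = c("a", "b"), control_freq = c(0, 0))
  effects <- data.frame(variant = "a", region = "tRNA",
                        coding_effect = "noncoding")
  ci <- data.frame(variant = character(0), ci = numeric(0))
  res <- runCascade(summaries, effects, ci)
  expect_equal(nrow(res), 2L)
  expect_equal(res$stage_failed[res$variant == "a"], "no_data")  # no CI row
  expect_equal(res$stage_failed[res$variant == "b"], "no_data")  # no effect
})

test_that("packaged cascade fixture reproduces its stage-count truth", {
  summaries <- read.delim(.pkg_extdata("synthetic_cascade_summaries.tsv"))
  effects <- read.delim(.pkg_extdata("synthetic_cascade_effects.tsv"))
  ci <- read.delim(.pkg_extdata("synthetic_cascade_ci.tsv"))
  mt <- read.delim(.pkg_extdata("synthetic_cascade_mitotip.tsv"))
  pred <- read.delim(.pkg_extdata("synthetic_cascade_predictors.tsv"))
  res <- runCascade(summaries, effects, ci, mt, pred)
  audit <- cascadeAudit(res)
  trna <- audit[audit$pathway == "tRNA", ]
  prot <- audit[audit$pathway == "protein", ]
  expect_equal(unlist(prot[-1], use.names = FALSE), c(70L, 60L, 55L, 14L))
  expect_equal(unlist(trna[-1], use.names = FALSE), c(20L, 16L, 14L, 3L))
  # independent brute-force evaluation of every variant
  reg <- predictorRegistry()
  for (i in seq_len(nrow(summaries))) {
    v <- summaries$variant[i]
    kind <- effects$region[match(v, effects$variant)]
    ce <- effects$coding_effect[match(v, effects$variant)]
    freq_ok <- summaries$carriers_controls[i] / summaries$n_controls[i] < 0.01
    ci_v <- ci$ci[match(v, ci$variant)]
    expected <- "not_prioritized"
    if (kind == "tRNA" && freq_ok && !is.na(ci_v) && ci_v > 0.75) {
      s <- mt$score[match(v, mt$variant)]
      if (!is.na(s) && (s > 16.25 || s >= 12.66)) expected <- "deleterious_tRNA"
    }
    if (kind == "protein" && ce == "nonsynonymous" && freq_ok &&
        !is.na(ci_v) && ci_v > 0.75) {
      d <- pred[pred$variant == v, ]
      del <- ifelse(reg$direction[match(d$tool, reg$tool)] == "higher",
                    d$score > reg$threshold[match(d$tool, reg$tool)],
                    d$score < reg$threshold[match(d$tool, reg$tool)])
      if (sum(del) > 6) expected <- "deleterious_protein"
    }
    expect_equal(res$final[res$variant == v], expected, info = v)
  }
  # the named variants behave as in the study: three tRNA PP/LP hits and a
  # protein variant deleterious by all 13 programs
  expect_setequal(res$variant[res$final == "deleterious_tRNA"],
                  c("5613_T>A", "5771_A>G", "7496_T>C"))
  expect_equal(res$consensus_votes[res$variant == "11622_A>G"], 13L)
  expect_equal(res$final[res$variant == "11622_A>G"], "deleterious_protein")
})

test_that("the cascade is monotone in votes and control frequency", {
  set.seed(21)
  reg <- predictorRegistry()
  for (rep in 1:30) {
    freq <- sample(c(0, 0.005, 0.009, 0.02), 1)
    nvote <- sample(0:12, 1)
    summaries <- data.frame(variant = "v", control_freq = freq)
    effects <- data.frame(variant = "v", region = "protein",
                          coding_effect = "nonsynonymous")
    ci <- data.frame(variant = "v", ci = runif(1, 0.5, 1))
    mkpred <- function(k) {
      if (k == 0) return(data.frame(variant = character(0),
                                    tool = character(0), score = numeric(0)))
      data.frame(variant = "v", tool = reg$tool[seq_len(k)],
                 score = ifelse(reg$direction[seq_len(k)] == "higher",
                                reg$threshold[seq_len(k)] + 1,
                                reg$threshold[seq_len(k)] - 1))
    }
    r1 <- runCascade(summaries, effects, ci, predictorScores = mkpred(nvote))
    r2 <- runCascade(summaries, effects, ci, predictorScores = mkpred(nvote + 1))
    # adding a deleterious vote never flips deleterious -> not
    if (r1$final == "deleterious_protein")
      expect_equal(r2$final, "deleterious_protein")
    # raising the control frequency never flips not -> prioritized
    s2 <- summaries; s2$control_freq <- min(1, freq + 0.01)
    r3 <- runCascade(s2, effects, ci, predictorScores = mkpred(nvote))
    if (r1$final == "not_prioritized")
      expect_equal(r3$final, "not_prioritized")
  }
})
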