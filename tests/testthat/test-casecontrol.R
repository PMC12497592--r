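test_that("odds ratio and Woolf interval match the closed form", {
  r <- oddsRatio(c(14, 132, 23, 97))
  expect_equal(r$odds_ratio, (14 * 97) / (132 * 23))
  expect_equal(round(r$odds_ratio, 3), 0.447)
  expect_equal(round(r$ci_low, 3), 0.219)
  expect_equal(round(r$ci_high, 3), 0.914)
  expect_false(r$correction_applied)
  expect_equal(oddsRatio(c(10, 10, 10, 10))$odds_ratio, 1)
})

test_that("zero cells trigger the Haldane 0.5 correction", {
  r <- oddsRatio(c(0, 10, 5, 5))
  expect_true(r$correction_applied)
  expect_equal(r$odds_ratio, (0.5 * 5.5) / (10.5 * 5.5))
  expect_true(r$ci_low <= r$odds_ratio && r$odds_ratio <= r$ci_high)
  expect_error(oddsRatio(c(0, 0, 0, 0)), "degenerate")
})

test_that("the Woolf interval contains the OR and tightens with sample size", {
  set.seed(77)
  for (i in 1:50) {
    t <- randomTable(50)
    r <- oddsRatio(t)
    expect_true(r$ci_low <= r$odds_ratio && r$odds_ratio <= r$ci_high)
    r10 <- oddsRatio(t * 10L)
    expect_lt(log(r10$ci_high / r10$ci_low), log(r$ci_high / r$ci_low))
    expect_equal(r10$odds_ratio, r$odds_ratio)
  }
})

test_that("Fisher exact matches hypergeometric enumeration", {
  expect_equal(fisherExact(c(2, 0, 0, 2)), 1 / 3)
  expect_equal(fisherExact(c(5, 5, 5, 5)), 1)
  expect_equal(fisherExact(c(0, 0, 3, 5)), 1)  # zero margin
  set.seed(5)
  for (i in 1:200) {
    n <- sample(1:30, 1)
    cells <- as.vector(stats::rmultinom(1, n, rep(0.25, 4)))
    expect_equal(fisherExact(cells),
                 fisherEnumOracle(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-10)
  }
})

test_that("Pearson chi-square matches the expected-count oracle", {
  r <- chiSquare(c(10, 10, 10, 10))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  t <- c(a = 14, b = 132, c = 23, d = 97)
  m <- matrix(t, 2, byrow = TRUE)
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  expect_equal(chiSquare(t)$statistic, sum((m - e)^2 / e))
  n <- sum(t)
  expect_equal(chiSquare(t)$statistic,
               n * (t[["a"]] * t[["d"]] - t[["b"]] * t[["c"]])^2 /
                 prod(rowSums(m)[1], rowSums(m)[2], colSums(m)[1],
                      colSums(m)[2]))
  # r x c generalization and degenerate margins
  m3 <- matrix(c(5, 1, 2, 9, 3, 4), 3, 2)
  expect_gte(chiSquare(m3)$statistic, 0)
  expect_true(chiSquare(c(0, 0, 3, 5))$degenerate)
  # Yates correction shrinks the statistic
  expect_lt(chiSquare(t, yates = TRUE)$statistic, chiSquare(t)$statistic)
})

test_that("binary-covariate logistic OR equals the contingency OR", {
  cells <- c(14, 132, 23, 97)
  exposure <- rep(c(1, 0, 1, 0), cells)
  outcome <- rep(c(1, 1, 0, 0), cells)
  fit <- logisticFit(exposure, outcome)
  expect_equal(fit$odds_ratio, (14 * 97) / (132 * 23), tolerance = 1e-8)
  expect_false(fit$separated)
  # independence gives slope 0, OR 1
  fit0 <- logisticFit(rep(c(1, 0, 1, 0), c(20, 20, 20, 20)),
                      rep(c(1, 1, 0, 0), c(20, 20, 20, 20)))
  expect_equal(fit0$beta, 0, tolerance = 1e-8)
  expect_equal(fit0$odds_ratio, 1, tolerance = 1e-8)
})

test_that("separated tables fall back to the corrected contingency OR", {
  exposure <- rep(c(1, 0, 1, 0), c(5, 5, 0, 10))
  outcome <- rep(c(1, 1, 0, 0), c(5, 5, 0, 10))
  expect_warning(fit <- logisticFit(exposure, outcome), "separation")
  expect_true(fit$separated)
  expect_equal(fit$odds_ratio, (5.5 * 10.5) / (5.5 * 0.5))
  expect_error(logisticFit(c(1, 1), c(1, 1)), "single class|constant")
})

test_that("Mann-Whitney U and exact p follow the enumeration oracle", {
  r <- mannWhitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$U), 0)
  expect_equal(r$p, 0.1)   # 2/20 over all C(6,3) rank assignments
  expect_true(r$exact)
  # identical multisets: U = nx * ny / 2 (midranks)
  r2 <- mannWhitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(unname(r2$U), 8)
  expect_equal(r2$p, 1)
  # exact and normal-approximation p agree within 0.01 for n = 8..10
  set.seed(9)
  for (n in 8:10) {
    x <- rnorm(n); y <- rnorm(n, 0.5)
    exact_p <- mannWhitney(x, y)$p
    approx_p <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(exact_p - approx_p), 0.01)
  }
})

test_that("Mann-Whitney holds its type-I error under the null", {
  set.seed(123)
  rej <- mean(replicate(1000, {
    mannWhitney(rnorm(146), rnorm(120))$p < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.02)
})

test_that("MAF floor excludes only SNPs rare in both groups", {
  expect_false(mafFilter(0.04, 0.04))
  expect_true(mafFilter(0.04, 0.06))
  expect_true(mafFilter(0.06, 0.04))
  expect_true(mafFilter(0.05, 0.05))  # the floor itself is retained
})

test_that("snpAssociation filters by MAF and reports raw plus BH p-values", {
  summaries <- data.frame(
    variant = c("1824_T>C", "3010_G>A", "100_A>G", "200_C>AC"),
    var_class = c("substitution", "substitution", "substitution", "insertion"),
    carriers_cases = c(30L, 14L, 4L, 50L),
    carriers_controls = c(10L, 23L, 4L, 50L),
    stringsAsFactors = FALSE)
  res <- snpAssociation(summaries, nCases = 146L, nControls = 120L)
  # 100_A>G has MAF ~2.7%/3.3% in cases/controls: excluded; the indel is
  # not a SNP
  expect_setequal(res$variant, c("1824_T>C", "3010_G>A"))
  d4 <- res[res$variant == "3010_G>A", ]
  expect_equal(round(d4$odds_ratio, 3), 0.447)
  expect_true(all(res$p_bh >= ifelse(is.na(res$p_wald), res$p_fisher,
                                     res$p_wald) - 1e-12))
  expect_true(all(c("p_fisher", "p_chi2", "p_wald", "p_bh") %in% names(res)))
})

test_that("haplogroup association reproduces the carrier-vs-rest tables", {
  pooled <- data.frame(haplogroup = c("D4", "F", "Others"),
                       cases = c(14L, 29L, 103L),
                       controls = c(23L, 22L, 75L))
  res <- haplogroupAssociation(pooled)
  expect_equal(round(res$odds_ratio[res$haplogroup == "D4"], 3), 0.447)
  expect_equal(nrow(res), 3L)
  expect_true(all(res$ci_low <= res$odds_ratio &
                    res$odds_ratio <= res$ci_high))
})

test_that("burden counting is per sample, per region, plus aggregates", {
  calls <- data.frame(
    sample_id = c("S1", "S1", "S1"),
    variant = c("4500_A>G", "4600_C>T", "4700_G>A"),  # all in ND2
    alt_reads = c(100L, 100L, 100L),
    total_reads = c(100L, 100L, 100L),
    stringsAsFactors = FALSE)
  co <- manualCohort(calls, c(S1 = "case", S2 = "control"))
  b <- burdenByRegion(co)
  ps <- b$per_sample
  expect_equal(ps$count[ps$sample_id == "S1" & ps$region == "ND2"], 3L)
  expect_equal(sum(ps$count[ps$sample_id == "S1" &
                              !ps$region %in% c("total", "coding")]), 3L)
  expect_equal(ps$count[ps$sample_id == "S1" & ps$region == "total"], 3L)
  expect_equal(ps$count[ps$sample_id == "S1" & ps$region == "coding"], 3L)
  expect_equal(sum(ps$count[ps$sample_id == "S2"]), 0L)
})

test_that("identical groups give p = 1 everywhere; shifts are detected", {
  calls <- data.frame(
    sample_id = rep(c("S1", "S2", "S3", "S4"), each = 2),
    variant = rep(c("4500_A>G", "750_A>G"), 4),
    alt_reads = 100L, total_reads = 100L, stringsAsFactors = FALSE)
  co <- manualCohort(calls, c(S1 = "case", S2 = "case",
                              S3 = "control", S4 = "control"))
  b <- burdenByRegion(co)
  expect_true(all(b$summary$p == 1))
  # heteroplasmic-only restriction drops homoplasmic calls
  bh <- burdenByRegion(co, heteroplasmicOnly = TRUE)
  expect_true(all(bh$per_sample$count == 0))
})

test_that("a designed +2 burden shift in one region is detected with power", {
  # cases draw Poisson(3), controls Poisson(1) variants in ND2 (n=100/100);
  # the region must be flagged at p < 0.05 in at least 80% of replicates
  set.seed(1234)
  hits <- replicate(200, {
    n_case <- rpois(100, 3); n_ctrl <- rpois(100, 1)
    counts <- c(n_case, n_ctrl)
    ids <- sprintf("S%03d", seq_len(200))
    groups <- setNames(rep(c("case", "control"), each = 100), ids)
    keep <- counts > 0
    calls <- data.frame(
      sample_id = rep(ids[keep], counts[keep]),
      variant = paste0(sample(4470:5511, sum(counts), replace = TRUE),
                       "_A>G"),
      alt_reads = 100L, total_reads = 100L, stringsAsFactors = FALSE)
    calls <- calls[!duplicated(calls[c("sample_id", "variant")]), ]
    co <- manualCohort(calls, groups)
    b <- burdenByRegion(co)
    b$summary$p[b$summary$region == "ND2"] < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("indel enrichment builds auditable tables and flags degeneracy", {
  summaries <- data.frame(
    variant = c(sprintf("%d_A>AC", 101:110), sprintf("%d_A>G", 201:220),
                sprintf("%d_C>T", 301:330)),
    position = c(101:110, 201:220, 301:330),
    var_class = c(rep("insertion", 10), rep("substitution", 50)),
    state_profile = c(rep("heteroplasmic_only", 30),
                      rep("homoplasmic_only", 30)),
    stringsAsFactors = FALSE)
  r <- indelEnrichment(summaries)
  expect_equal(sum(r$state_table), 60)
  expect_equal(unclass(r$state_table)[1, 1], 10)  # het-only indels
  expect_equal(unclass(r$state_table)[2, 1], 0)
  expect_lt(r$p_fisher_state, 0.05)
  expect_lt(r$p_chi2_state, 0.05)
  expect_equal(sum(r$region_table), 60)
  # all-SNV input degenerates rather than erroring
  s2 <- summaries; s2$var_class <- "substitution"
  r2 <- indelEnrichment(s2)
  expect_true(r2$degenerate)
  expect_true(is.na(r2$p_fisher_state))
})
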