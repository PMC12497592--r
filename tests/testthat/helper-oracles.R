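# Independent oracles and small in-code fixtures shared across tests.

# Two-sided Fisher p by explicit hypergeometric enumeration (independent of
# stats::fisher.test): sum the point probabilities of all tables with the
# observed margins that are no more probable than the observed one.
fisherEnumOracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, ks) + lchoose(r2, c1 - ks) - lchoose(n, c1)
  p <- exp(logp)
  p_obs <- p[ks == a]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by enumeration of all rank assignments
# (tie-free samples only).
mwEnumOracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  ranks <- rank(c(x, y))
  u_obs <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  all_u <- apply(utils::combn(nx + ny, nx), 2L, function(idx) {
    sum(seq_len(nx + ny)[idx]) - nx * (nx + 1) / 2
  })
  lo <- mean(all_u <= u_obs)
  hi <- mean(all_u >= u_obs)
  min(1, 2 * min(lo, hi))
}

# Toy 16-bp genome with a single heavy-strand protein gene at 4..12.
toyGenome <- function(seq = "AAAATGGCCTAAAAAA", strand = "heavy") {
  gm <- new("MitoGenomeMap",
            features = data.frame(
              name = "pep", start = 4L, end = 12L, strand = strand,
              kind = "protein", wrap = FALSE, incomplete_stop = FALSE,
              stringsAsFactors = FALSE),
            genomeLength = 16L)
  list(gm = gm, ref = seq)
}

# Minimal phylotree: root -> H1 (4 vars) -> H1a (adds none, same closure).
toyTree <- function() {
  nodes <- data.frame(
    haplogroup = c("ROOT", "H1", "H1a", "K2"),
    parent = c(NA, "ROOT", "H1", "ROOT"),
    defining_variants = c("", "100_A>G,200_C>T,300_G>A,400_T>C",
                          "", "500_A>G,600_C>T"),
    stringsAsFactors = FALSE)
  new("Phylotree", nodes = nodes, root = "ROOT")
}

# A cohort built directly from a calls specification (no simulation).
manualCohort <- function(calls, groups) {
  samples <- data.frame(sample_id = names(groups), group = unname(groups),
                        stringsAsFactors = FALSE)
  makeCohort(calls, samples)
}

.pkg_extdata <- function(f) {
  system.file("extdata", f, package = "mitocase", mustWork = TRUE)
}

randomTable <- function(nmax = 200) {
  repeat {
    t <- c(a = sample(0:nmax, 1), b = sample(1:nmax, 1),
           c = sample(1:nmax, 1), d = sample(0:nmax, 1))
    if (all(t > 0)) return(t)
  }
}
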