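#' Read a population x haplogroup frequency matrix
#'
#' CSV with a `population` column followed by one column per haplogroup.
#' Rows are checked to sum to 1 within `tol`; rows that do not are
#' renormalized with a message.
#'
#' @param path CSV file.
#' @param tol row-sum tolerance (default 1e-6).
#' @return numeric matrix (populations x haplogroups).
#' @export
readFrequencyMatrix <- function(path, tol = 1e-6) {
  d <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot("population" %in% names(d))
  m <- as.matrix(d[setdiff(names(d), "population")])
  rownames(m) <- d$population
  storage.mode(m) <- "double"
  if (any(m < 0 | m > 1)) stop("frequencies must lie in [0, 1]")
  rs <- rowSums(m)
  off <- abs(rs - 1) > tol
  if (any(off)) {
    message("renormalizing ", sum(off), " row(s) not summing to 1")
    m[off, ] <- m[off, ] / rs[off]
  }
  m
}

#' Packaged synthetic population frequency panel
#'
#' Haplogroup frequency profiles for 23 synthetic Chinese populations
#' with a loose geographic structure (southwestern, southeastern and
#' northern archetypes).  Synthetic data for demonstrating the PCA
#' machinery; not curated real reference populations.
#'
#' @return numeric matrix (populations x haplogroups).
#' @export
defaultPopulationFrequencies <- function() {
  readFrequencyMatrix(.extdata("synthetic_population_haplogroup_freq.csv"))
}

#' PCA of haplogroup frequency profiles
#'
#' Column-centers the frequency matrix and eigen-decomposes its
#' covariance (no scaling by default; `mode = "correlation"` standardizes
#' columns first).  Components are ordered by decreasing eigenvalue;
#' `variance_explained` are eigenvalue fractions of the total variance.
#' Sign convention: each loading vector's largest-magnitude entry is made
#' positive (scores flipped accordingly) so results are reproducible
#' across platforms.
#'
#' @param fm numeric matrix (populations x haplogroups), e.g. from
#'   [readFrequencyMatrix()].
#' @param nComponents number of components to keep (default: full rank).
#' @param mode `"covariance"` (default) or `"correlation"`.
#' @return list `scores`, `loadings`, `variance_explained`, `degenerate`.
#' @export
pcaHaplogroupFreq <- function(fm, nComponents = NULL,
                              mode = c("covariance", "correlation")) {
  mode <- match.arg(mode)
  if (nrow(fm) < 2L) stop("PCA needs at least 2 populations")
  max_k <- min(nrow(fm) - 1L, ncol(fm))
  if (is.null(nComponents)) nComponents <- max_k
  if (nComponents > max_k)
    stop("nComponents must be <= min(rows - 1, cols) = ", max_k)
  if (mode == "correlation") {
    sds <- apply(fm, 2L, sd)
    if (any(sds == 0)) {
      fm <- fm[, sds > 0, drop = FALSE]
      sds <- sds[sds > 0]
    }
  }
  total_var <- sum(apply(scale(fm, center = TRUE,
                               scale = (mode == "correlation")), 2L,
                         function(x) sum(x^2)) / (nrow(fm) - 1L))
  if (total_var < .Machine$double.eps * 100) {
    k <- nComponents
    return(list(scores = matrix(0, nrow(fm), k,
                                dimnames = list(rownames(fm),
                                                paste0("PC", seq_len(k)))),
                loadings = matrix(0, ncol(fm), k,
                                  dimnames = list(colnames(fm),
                                                  paste0("PC", seq_len(k)))),
                variance_explained = rep(0, k), degenerate = TRUE))
  }
  p <- prcomp(fm, center = TRUE, scale. = (mode == "correlation"))
  k <- nComponents
  scores <- p$x[, seq_len(k), drop = FALSE]
  loadings <- p$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ve <- p$sdev^2 / sum(p$sdev^2)
  list(scores = scores, loadings = loadings,
       variance_explained = ve[seq_len(k)], degenerate = FALSE)
}

#' Rank populations by distance in PC space
#'
#' Euclidean distances from the query population's scores to every other
#' population, ranked ascending; ties break lexicographically.
#'
#' @param scores score matrix from [pcaHaplogroupFreq()].
#' @param query population (row) name.
#' @return `data.frame`: `population`, `distance`, ranked.
#' @export
nearestPopulations <- function(scores, query) {
  if (!query %in% rownames(scores)) stop("unknown population: ", query)
  q <- scores[query, ]
  others <- setdiff(rownames(scores), query)
  d <- vapply(others, function(p) sqrt(sum((scores[p, ] - q)^2)), 0)
  ord <- order(d, others)
  data.frame(population = others[ord], distance = unname(d[ord]),
             stringsAsFactors = FALSE)
}
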