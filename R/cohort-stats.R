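#' Wilcoxon rank-sum test for two groups
#'
#' Exact enumeration when the combined sample size is at most 12 and the data
#' are tie-free; otherwise a normal approximation with midranks and tie
#' correction plus a continuity correction, so the approximate path tracks
#' the exact one closely even at moderate n.
#'
#' @param a,b numeric vectors (both nonempty).
#' @param normal_approx force the approximate path (for diagnostics).
#' @return list with `statistic` (Mann-Whitney U of group `a`), `p.value`,
#'   `method`.
#' @export
wilcoxonRankSum <- function(a, b, normal_approx = FALSE) {
  if (length(a) == 0 || length(b) == 0) stop("both groups must be nonempty")
  n <- length(a) + length(b)
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !normal_approx && n <= 12 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = !exact))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Likelihood-ratio (G) chi-squared test for a 2x2 table
#'
#' `G = 2 * sum(O * log(O / E))` with zero-count cells contributing zero;
#' the p-value is from the chi-squared distribution with one degree of
#' freedom. G is invariant to transposing the table.
#'
#' @param counts 2x2 numeric matrix of observed counts with positive margins.
#' @return list with `statistic` (G) and `p.value`.
#' @export
likelihoodRatioChi2 <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(identical(dim(counts), c(2L, 2L)), all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("all margins must be positive")
  E <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  terms <- ifelse(counts == 0, 0, counts * log(counts / E))
  G <- 2 * sum(terms)
  list(statistic = G, p.value = stats::pchisq(G, df = 1, lower.tail = FALSE))
}

#' Per-group median and interquartile range
#'
#' Quartiles use linear interpolation (`stats::quantile` type 7).
#'
#' @param values numeric vector.
#' @param outcome grouping vector/factor of the same length.
#' @return data.frame with one row per group: `group`, `n`, `q1`, `median`,
#'   `q3`.
#' @export
groupMedianIQR <- function(values, outcome) {
  outcome <- as.factor(outcome)
  if (any(table(outcome) == 0)) stop("each group must be nonempty")
  out <- do.call(rbind, lapply(levels(outcome), function(g) {
    v <- values[outcome == g]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(group = g, n = length(v), q1 = q[1], median = q[2], q3 = q[3],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' PCA variance profile
#'
#' Per-component variance fractions from the squared singular values of the
#' column-centered (and optionally standardized) matrix, with the cumulative
#' profile and the smallest number of components reaching a target fraction.
#'
#' @param mat samples x features numeric matrix (>= 2 rows and columns).
#' @param standardize scale columns to unit variance first (default `TRUE`;
#'   zero-variance columns are dropped from the decomposition).
#' @return list of class `VarianceProfile` with `fraction`, `cumulative`,
#'   and `n_components_for(f)`.
#' @export
pcaVarianceProfile <- function(mat, standardize = TRUE) {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) >= 2, ncol(mat) >= 2)
  sdv <- apply(mat, 2L, stats::sd)
  if (all(sdv == 0)) stop("matrix is constant; PCA undefined")
  if (standardize) mat <- mat[, sdv > 0, drop = FALSE]
  pc <- stats::prcomp(mat, center = TRUE, scale. = standardize)
  v <- pc$sdev^2
  frac <- v / sum(v)
  cum <- cumsum(frac)
  structure(list(fraction = frac, cumulative = cum,
                 n_components_for = function(f) {
                   stopifnot(f > 0, f <= 1)
                   which(cum >= f - 1e-12)[1]
                 }),
            class = "VarianceProfile")
}

#' @export
print.VarianceProfile <- function(x, ...) {
  cat("VarianceProfile:", length(x$fraction), "components; PC1",
      sprintf("%.1f%%;", 100 * x$fraction[1]),
      x$n_components_for(0.8), "components reach 80%\n")
  invisible(x)
}

#' Hierarchical clustering leaf order
#'
#' Agglomerative clustering of the rows of a matrix (default Euclidean
#' distance, complete linkage) returning the dendrogram leaf order.
#' Deterministic for a fixed input: `hclust` breaks ties by merge index.
#'
#' @param mat numeric matrix (>= 2 rows).
#' @param distance distance measure for [stats::dist()].
#' @param linkage agglomeration method for [stats::hclust()].
#' @return integer vector: row indices in dendrogram leaf order, with the
#'   `hclust` object as attribute `"hclust"`.
#' @export
hierarchicalClusterOrder <- function(mat, distance = "euclidean",
                                     linkage = "complete") {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("need at least 2 items to cluster")
  hc <- stats::hclust(stats::dist(mat, method = distance), method = linkage)
  structure(hc$order, hclust = hc)
}

#' Univariate metabolite screen
#'
#' Wilcoxon rank-sum p-value and per-group median/IQR for every metabolite,
#' comparing survivors and non-survivors. Raw p-values are reported (the
#' ensemble score, not the p-value, is the prioritization instrument); a
#' Benjamini-Hochberg column is emitted alongside for reference but never
#' used for ranking.
#'
#' @param experiment a [MetaboliteExperiment-class] with no missing
#'   abundances (post-imputation).
#' @param outcomes optional outcome override.
#' @return data.frame, one row per metabolite: group medians/IQRs, `p_value`,
#'   `p_adjust_bh`.
#' @export
univariateScreen <- function(experiment, outcomes = NULL) {
  if (is.null(outcomes)) outcomes <- sampleOutcome(experiment)
  yf <- .as_y(outcomes)
  ab <- abundance(experiment)
  res <- do.call(rbind, lapply(seq_len(nrow(ab)), function(j) {
    v <- ab[j, ]
    died <- v[yf == "died"]; surv <- v[yf == "survived"]
    w <- wilcoxonRankSum(died, surv)
    qs <- stats::quantile(surv, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    qd <- stats::quantile(died, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(metabolite = rownames(ab)[j],
               median_survived = qs[2], q1_survived = qs[1],
               q3_survived = qs[3],
               median_died = qd[2], q1_died = qd[1], q3_died = qd[3],
               p_value = w$p.value, stringsAsFactors = FALSE)
  }))
  res$p_adjust_bh <- stats::p.adjust(res$p_value, method = "BH")
  rownames(res) <- NULL
  res
}
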