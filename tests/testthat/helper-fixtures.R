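# Hand-built tiny experiment: p metabolites x n samples with optional mask.
tiny_experiment <- function(values, mask = NULL, is_drug = NULL,
                            outcome = NULL, scale = "raw") {
  p <- nrow(values); n <- ncol(values)
  mids <- sprintf("m%02d", seq_len(p))
  sids <- sprintf("s%02d", seq_len(n))
  dimnames(values) <- list(mids, sids)
  if (!is.null(mask)) dimnames(mask) <- list(mids, sids)
  if (is.null(is_drug)) is_drug <- rep(FALSE, p)
  cd <- data.frame(row.names = sids)
  if (!is.null(outcome)) cd$outcome <- outcome
  MetaboliteExperiment(
    abundance = values, belowLOD = mask,
    rowData = data.frame(metabolite = paste0("met-", mids),
                         super_pathway = rep_len(c("Amino acid", "Lipid"), p),
                         sub_pathway = "sub", is_drug = is_drug,
                         row.names = mids),
    colData = cd, scale = scale)
}

# Independent average-precision oracle: loop over distinct thresholds,
# count TP/FP directly, accumulate delta-recall x precision.
ap_oracle <- function(scores, labels) {
  P <- sum(labels == 1)
  th <- sort(unique(scores), decreasing = TRUE)
  ap <- 0; prev_rec <- 0
  for (t in th) {
    tp <- sum(scores >= t & labels == 1)
    fp <- sum(scores >= t & labels == 0)
    rec <- tp / P
    prec <- tp / (tp + fp)
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# Independent ROC-AUC oracle: concordant pair counting with half-ties.
roc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# Separable multi-feature toy: feature 1 tracks the outcome, rest are noise.
toy_separable <- function(n = 60, p = 5, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  X <- matrix(rnorm(n * p), n, p)
  X[, 1] <- 2 * y + 0.01 * rnorm(n)
  colnames(X) <- paste0("f", seq_len(p))
  list(X = scale(X), y = y)
}

# Wrap a samples x features matrix as a log10-scale experiment (no mask).
tiny_noise_experiment <- function(X, y) {
  MetaboliteExperiment(
    abundance = t(X),
    rowData = data.frame(metabolite = colnames(X),
                         super_pathway = "Amino acid", sub_pathway = "sub",
                         is_drug = FALSE, row.names = colnames(X)),
    colData = data.frame(outcome = ifelse(y == 1, "died", "survived"),
                         row.names = rownames(X) %||% paste0("s", seq_len(nrow(X)))),
    scale = "log10")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

small_pipeline_config <- function(seed = 7, families = c("lasso_logistic",
                                                         "svm"),
                                  n_repeats = 2) {
  pipelineConfig(
    synthetic = syntheticConfig(n_samples = 40, n_metabolites = 60,
                                n_effect_metabolites = 5, seed = seed),
    families = families, n_repeats = n_repeats, top_n = 10, seed = seed)
}
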