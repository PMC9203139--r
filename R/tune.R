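# Fold-safe preparation: imputation fill values and standardization
# parameters are computed on the training fold only, then applied to the
# held-out fold. Operates on samples x metabolites matrices carrying the
# below-LOD mask.
.prepare_fold <- function(Xs, mask, train_idx, test_idx, strategy = "half_min") {
  Xtr <- Xs[train_idx, , drop = FALSE]
  Xte <- Xs[test_idx, , drop = FALSE]
  Mtr <- mask[train_idx, , drop = FALSE]
  Mte <- mask[test_idx, , drop = FALSE]
  fills <- vapply(seq_len(ncol(Xs)), function(j) {
    obs <- Xtr[!Mtr[, j] & !is.na(Xtr[, j]), j]
    if (length(obs) == 0) return(NA_real_)
    .impute_fill(obs, strategy)
  }, numeric(1))
  if (anyNA(fills))
    stop("a metabolite has no observed training values in a fold")
  for (j in seq_len(ncol(Xs))) {
    Xtr[Mtr[, j] | is.na(Xtr[, j]), j] <- fills[j]
    Xte[Mte[, j] | is.na(Xte[, j]), j] <- fills[j]
  }
  sc <- suppressWarnings(standardizeFold(Xtr, Xte))
  list(train = sc$train, test = sc$applied[[1]],
       fill = fills, center = sc$center, scale = sc$scale)
}

#' Tune one model family under the precision-recall curve
#'
#' For every hyperparameter grid row, fits on each training fold of the plan
#' (imputation and scaling parameters computed on that training fold only)
#' and scores the held-out fold; the grid row with the highest mean held-out
#' PR-AUC across all `n_repeats * n_folds` splits wins, ties going to the
#' earlier (more regularized) grid row. The final model is refit on all
#' samples at the winning hyperparameters and its innate importance vector
#' extracted from that refit.
#'
#' @param spec a [modelSpec()].
#' @param experiment a filtered, log10-scale [MetaboliteExperiment-class];
#'   masked cells may still be unimputed (they are imputed fold-safely).
#' @param outcomes binary outcome vector/factor (defaults to the experiment's
#'   `outcome` column).
#' @param fold_plan a [makeFoldPlan()] over the same samples.
#' @param threshold classification threshold for sensitivity/specificity
#'   reporting (default 0.5).
#' @param imputation_strategy see [preprocessConfig()].
#' @param seed integer seed for the family's stochastic components.
#' @return list of class `FittedModelResult`: `family_id`,
#'   `best_hyperparams`, `metrics` (one row per split: `repeat_index`,
#'   `fold_index`, `pr_auc`, `roc_auc`, `sensitivity`, `specificity`),
#'   `summary` (mean/sd per metric), `grid_pr_auc` (mean PR-AUC per grid
#'   row), `importance` ([importanceVector()] of the full-data refit),
#'   `selection` (character ids "ranked highly" by this family).
#' @export
tuneModel <- function(spec, experiment, outcomes = NULL, fold_plan,
                      threshold = 0.5, imputation_strategy = "half_min",
                      seed = 1L) {
  stopifnot(inherits(spec, "ModelSpec"), inherits(fold_plan, "FoldPlan"))
  if (nrow(spec$grid) == 0) stop("empty hyperparameter grid")
  if (is.null(outcomes)) outcomes <- sampleOutcome(experiment)
  yf <- .as_y(outcomes)
  y01 <- as.integer(yf == "died")
  stopifnot(length(y01) == fold_plan$n)

  Xs <- assayMatrix(experiment)
  mask <- t(belowLOD(experiment))
  G <- nrow(spec$grid)
  nsplit <- length(fold_plan$splits)
  pr <- roc <- sens <- spc <- matrix(NA_real_, nsplit, G)

  path_fn <- paste0(".path_", spec$family_id)
  has_path <- exists(path_fn, mode = "function",
                     envir = asNamespace("metaboConsensus"))

  for (i in seq_len(nsplit)) {
    sp <- fold_plan$splits[[i]]
    prep <- .prepare_fold(Xs, mask, sp$train, sp$test, imputation_strategy)
    ytr <- y01[sp$train]; yte <- y01[sp$test]
    yftr <- yf[sp$train]
    fold_seed <- .substream(seed, 1000L + i)
    if (has_path) {
      scorer <- get(path_fn, mode = "function",
                    envir = asNamespace("metaboConsensus"))(
        prep$train, ytr, yftr, spec$grid, fold_seed)
      S <- scorer(prep$test)
    } else {
      S <- sapply(seq_len(G), function(g) {
        fit <- fitModel(spec, prep$train, yftr,
                        as.list(spec$grid[g, , drop = FALSE]),
                        seed = .substream(fold_seed, g))
        scoreModel(fit, prep$test)
      })
    }
    if (is.null(dim(S))) S <- matrix(S, nrow = length(sp$test))
    for (g in seq_len(G)) {
      pr[i, g] <- prAUC(S[, g], yte)
      roc[i, g] <- rocAUC(S[, g], yte)
      cm <- suppressWarnings(confusionMetrics(S[, g], yte, threshold))
      sens[i, g] <- cm["sensitivity"]; spc[i, g] <- cm["specificity"]
    }
  }

  grid_pr <- colMeans(pr)
  best <- which.max(grid_pr)  # first max: earlier rows are more regularized
  best_hyper <- as.list(spec$grid[best, , drop = FALSE])

  # full-data refit at tuned hyperparameters
  full <- imputeMissing(experiment,
                        preprocessConfig(imputation_strategy =
                                           imputation_strategy))$experiment
  Xfull <- suppressWarnings(standardizeFold(assayMatrix(full)))$train
  refit <- fitModel(spec, Xfull, yf, best_hyper, seed = .substream(seed, 7L))
  iv <- importanceVector(refit)
  selection <- topSelection(iv, rule = spec$selection_mode, n = spec$top_n)

  metrics <- data.frame(
    repeat_index = vapply(fold_plan$splits, `[[`, integer(1), "repeat_index"),
    fold_index = vapply(fold_plan$splits, `[[`, integer(1), "fold_index"),
    pr_auc = pr[, best], roc_auc = roc[, best],
    sensitivity = sens[, best], specificity = spc[, best])
  summ <- vapply(metrics[, c("pr_auc", "roc_auc", "sensitivity",
                             "specificity")],
                 function(v) c(mean = mean(v, na.rm = TRUE),
                               sd = stats::sd(v, na.rm = TRUE)),
                 numeric(2))
  structure(list(family_id = spec$family_id, best_hyperparams = best_hyper,
                 metrics = metrics, summary = summ,
                 grid_pr_auc = stats::setNames(grid_pr,
                                               apply(spec$grid, 1L, paste,
                                                     collapse = "/")),
                 importance = iv, selection = selection, fitted = refit),
            class = "FittedModelResult")
}

#' @export
print.FittedModelResult <- function(x, ...) {
  cat("FittedModelResult [", x$family_id, "]\n", sep = "")
  cat("  best hyperparameters:",
      paste(names(x$best_hyperparams), unlist(x$best_hyperparams),
            sep = "=", collapse = ", "), "\n")
  cat(sprintf("  mean PR-AUC %.3f | ROC-AUC %.3f | sens %.3f | spec %.3f\n",
              x$summary["mean", "pr_auc"], x$summary["mean", "roc_auc"],
              x$summary["mean", "sensitivity"],
              x$summary["mean", "specificity"]))
  cat("  selected metabolites:", length(x$selection), "\n")
  invisible(x)
}
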