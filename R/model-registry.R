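#' Model family specification
#'
#' @param family_id one of `"pls_da"`, `"nearest_shrunken_centroids"`,
#'   `"random_forest"`, `"svm"`, `"random_knn"`, `"ada_boost_bag"`,
#'   `"lasso_logistic"`, `"penalized_logistic"`.
#' @param grid data.frame of candidate hyperparameter rows, ordered most
#'   regularized / least complex first (this order is the tie-break when mean
#'   cross-validated PR-AUC ties).
#' @param selection_mode `"native"` (the family's intrinsic sparse support;
#'   only for families with one) or `"top_n"`.
#' @param top_n how many top-importance metabolites count as "ranked highly"
#'   under `top_n` selection (default 20).
#' @return list of class `ModelSpec`.
#' @export
modelSpec <- function(family_id, grid, selection_mode = c("top_n", "native"),
                      top_n = 20L) {
  selection_mode <- match.arg(selection_mode)
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  if (selection_mode == "native" &&
      !family_id %in% c("lasso_logistic", "nearest_shrunken_centroids"))
    stop("native selection requires a family with an intrinsic sparse solution")
  structure(list(family_id = family_id, grid = grid,
                 selection_mode = selection_mode, top_n = as.integer(top_n)),
            class = "ModelSpec")
}

.FAMILIES <- c("pls_da", "nearest_shrunken_centroids", "random_forest",
               "svm", "random_knn", "ada_boost_bag", "lasso_logistic",
               "penalized_logistic")

#' Default registry of classifier families
#'
#' Eight families: the seven machine-learning approaches (PLS-DA, nearest
#' shrunken centroids, random forests, linear-kernel SVM, random-subspace
#' KNN, adaptive boosting with stumps, lasso logistic regression) plus
#' elastic-net penalized logistic regression, in a fixed deterministic order.
#' Default grids are small and documented per family: a 10-value relative
#' penalty path for the penalized regressions, 1-5 PLS components, a 10-value
#' shrinkage path for shrunken centroids, 500-tree forests at two mtry
#' settings, three SVM costs, three neighborhood sizes, and two boosting
#' round counts. The grid row order encodes the complexity tie-break
#' (stronger regularization / fewer components preferred).
#'
#' @param families optional character subset of family ids to include.
#' @param top_n "ranked highly" cut for non-sparse families (default 20).
#' @return named list of [modelSpec()] objects.
#' @export
defaultRegistry <- function(families = NULL, top_n = 20L) {
  lam <- 10^seq(0, -3, length.out = 10)  # relative to per-fit lambda_max
  specs <- list(
    pls_da = modelSpec("pls_da", data.frame(ncomp = 1:5), "top_n", top_n),
    nearest_shrunken_centroids = modelSpec(
      "nearest_shrunken_centroids",
      data.frame(threshold_frac = seq(0.9, 0, length.out = 10)),
      "native", top_n),
    random_forest = modelSpec(
      "random_forest", data.frame(mtry_prop = c(0.1, 1 / 3)), "top_n", top_n),
    svm = modelSpec("svm", data.frame(cost = c(0.1, 1, 10)), "top_n", top_n),
    random_knn = modelSpec("random_knn", data.frame(k = c(7L, 5L, 3L)),
                           "top_n", top_n),
    ada_boost_bag = modelSpec("ada_boost_bag",
                              data.frame(n_rounds = c(25L, 50L)),
                              "top_n", top_n),
    lasso_logistic = modelSpec("lasso_logistic",
                               data.frame(lambda_frac = lam), "native", top_n),
    penalized_logistic = modelSpec("penalized_logistic",
                                   data.frame(lambda_frac = lam), "top_n",
                                   top_n))
  if (!is.null(families)) {
    bad <- setdiff(families, names(specs))
    if (length(bad)) stop("unknown families: ", paste(bad, collapse = ", "))
    specs <- specs[families]
  }
  specs
}

.as_y <- function(y) {
  if (is.factor(y)) yf <- factor(as.character(y), levels = c("survived", "died"))
  else yf <- factor(ifelse(as.integer(y) == 1, "died", "survived"),
                    levels = c("survived", "died"))
  if (any(is.na(yf))) stop("outcome must be 0/1 or survived/died")
  if (length(unique(yf)) < 2) stop("outcome has a single class; cannot fit")
  yf
}

.clip01 <- function(x) pmin(1, pmax(0, x))

# ---- family internals -------------------------------------------------------
# Each family implements:
#   .fit_<fam>(X, y01, yf, hyper, seed)        -> model object
#   .score_<fam>(model, Xnew)                  -> death-probability scores
#   .imp_<fam>(model)                          -> list(importance, native)
# and optionally a shared-path trainer used by tuneModel:
#   .path_<fam>(X, y01, yf, grid, seed)        -> function(Xnew) n x G matrix

## PLS-DA (mixOmics); VIP scores at the tuned component count
.fit_pls_da <- function(X, y01, yf, hyper, seed) {
  fit <- mixOmics::plsda(X, yf, ncomp = hyper$ncomp)
  list(fit = fit, ncomp = hyper$ncomp)
}
.score_pls_da <- function(model, Xnew) {
  p <- stats::predict(model$fit, Xnew)$predict[, "died", model$ncomp]
  .clip01(p)
}
.imp_pls_da <- function(model) {
  v <- mixOmics::vip(model$fit)
  list(importance = v[, model$ncomp], native = NULL)
}
.path_pls_da <- function(X, y01, yf, grid, seed) {
  fit <- mixOmics::plsda(X, yf, ncomp = max(grid$ncomp))
  function(Xnew) {
    pr <- stats::predict(fit, Xnew)$predict
    sapply(grid$ncomp, function(nc) .clip01(pr[, "died", nc]))
  }
}

## Nearest shrunken centroids (soft-thresholded class centroids)
.nsc_stats <- function(X, yf) {
  n <- nrow(X); classes <- levels(yf)
  nk <- table(yf)
  xbar <- colMeans(X)
  cent <- t(sapply(classes, function(k) colMeans(X[yf == k, , drop = FALSE])))
  ss <- 0
  for (k in classes)
    ss <- ss + colSums(sweep(X[yf == k, , drop = FALSE], 2L, cent[k, ])^2)
  s <- sqrt(ss / (n - length(classes)))
  s0 <- stats::median(s)
  mk <- sqrt(1 / as.numeric(nk) + 1 / n); names(mk) <- classes
  d <- sweep(sweep(cent, 2L, xbar), 1L, mk, `/`)
  d <- sweep(d, 2L, s + s0, `/`)
  list(xbar = xbar, s = s, s0 = s0, mk = mk, d = d,
       prior = as.numeric(nk) / n, classes = classes)
}
.nsc_model <- function(st, threshold_frac) {
  delta <- threshold_frac * max(abs(st$d))
  dsh <- sign(st$d) * pmax(abs(st$d) - delta, 0)
  cent_sh <- sweep(sweep(dsh, 2L, st$s + st$s0, `*`), 1L, st$mk, `*`)
  cent_sh <- sweep(cent_sh, 2L, st$xbar, `+`)
  list(st = st, dsh = dsh, cent_sh = cent_sh)
}
.nsc_score <- function(m, Xnew) {
  st <- m$st
  disc <- sapply(seq_along(st$classes), function(k) {
    rowSums(sweep(sweep(Xnew, 2L, m$cent_sh[k, ]), 2L, st$s + st$s0, `/`)^2) -
      2 * log(st$prior[k])
  })
  w <- exp(-(disc - apply(disc, 1L, min)) / 2)
  (w / rowSums(w))[, match("died", st$classes)]
}
.fit_nearest_shrunken_centroids <- function(X, y01, yf, hyper, seed)
  .nsc_model(.nsc_stats(X, yf), hyper$threshold_frac)
.score_nearest_shrunken_centroids <- function(model, Xnew)
  .nsc_score(model, Xnew)
.imp_nearest_shrunken_centroids <- function(model) {
  imp <- apply(abs(model$dsh), 2L, max)
  list(importance = imp, native = imp > 0)
}
.path_nearest_shrunken_centroids <- function(X, y01, yf, grid, seed) {
  st <- .nsc_stats(X, yf)
  models <- lapply(grid$threshold_frac, function(f) .nsc_model(st, f))
  function(Xnew) sapply(models, .nsc_score, Xnew = Xnew)
}

## Random forest (impurity importance)
.fit_random_forest <- function(X, y01, yf, hyper, seed) {
  mtry <- max(1L, floor(hyper$mtry_prop * ncol(X)))
  fit <- .with_seed(seed,
                    randomForest::randomForest(x = X, y = yf, ntree = 500,
                                               mtry = mtry))
  list(fit = fit)
}
.score_random_forest <- function(model, Xnew)
  stats::predict(model$fit, Xnew, type = "prob")[, "died"]
.imp_random_forest <- function(model) {
  imp <- model$fit$importance[, "MeanDecreaseGini"]
  list(importance = imp, native = NULL)
}

## Linear-kernel SVM; importance = |weight vector|
.fit_svm <- function(X, y01, yf, hyper, seed) {
  fit <- .with_seed(seed,
                    e1071::svm(x = X, y = yf, kernel = "linear",
                               cost = hyper$cost, probability = TRUE,
                               scale = FALSE))
  list(fit = fit)
}
.score_svm <- function(model, Xnew) {
  pr <- stats::predict(model$fit, Xnew, probability = TRUE)
  attr(pr, "probabilities")[, "died"]
}
.imp_svm <- function(model) {
  w <- drop(t(model$fit$coefs) %*% model$fit$SV)
  list(importance = abs(w), native = NULL)
}

## Random-subspace KNN ensemble; importance = feature support frequency
## among the better-performing half of the base learners
.fit_random_knn <- function(X, y01, yf, hyper, seed, n_learners = 100L) {
  p <- ncol(X)
  m <- max(2L, min(p, ceiling(sqrt(p))))
  subsets <- .with_seed(.substream(seed, 31L),
                        lapply(seq_len(n_learners),
                               function(i) sort(sample.int(p, m))))
  acc <- .with_seed(.substream(seed, 32L), vapply(subsets, function(S) {
    pred <- class::knn.cv(X[, S, drop = FALSE], yf, k = hyper$k)
    mean(pred == yf)
  }, numeric(1)))
  list(X = X, yf = yf, k = hyper$k, subsets = subsets, acc = acc, p = p,
       seed = seed)
}
.score_random_knn <- function(model, Xnew) {
  votes <- .with_seed(.substream(model$seed, 33L), vapply(model$subsets,
    function(S) {
      pred <- class::knn(model$X[, S, drop = FALSE],
                         Xnew[, S, drop = FALSE], model$yf,
                         k = model$k, prob = TRUE)
      pwin <- attr(pred, "prob")
      ifelse(pred == "died", pwin, 1 - pwin)
    }, numeric(nrow(Xnew))))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = 1L)
  rowMeans(votes)
}
.imp_random_knn <- function(model) {
  good <- model$acc >= stats::median(model$acc)
  counts <- tabulate(unlist(model$subsets[good]), nbins = model$p)
  imp <- counts / max(1L, sum(good))
  names(imp) <- colnames(model$X)
  list(importance = imp, native = NULL)
}

## Adaptive boosting (AdaBoost.M1) over depth-1 rpart stumps;
## importance = total alpha credited to the splitting feature
.fit_ada_boost_bag <- function(X, y01, yf, hyper, seed) {
  n <- nrow(X)
  df <- data.frame(.y = yf, X, check.names = FALSE)
  w <- rep(1 / n, n)
  ys <- ifelse(y01 == 1, 1, -1)
  ctrl <- rpart::rpart.control(maxdepth = 1, cp = -1, minsplit = 2,
                               minbucket = 1, xval = 0, maxcompete = 0,
                               maxsurrogate = 0, usesurrogate = 0)
  stumps <- list(); alphas <- numeric(0)
  for (t in seq_len(hyper$n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = ctrl)
    pred <- ifelse(stats::predict(fit, df, type = "class") == "died", 1, -1)
    err <- sum(w * (pred != ys))
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(-alpha * ys * pred)
    w <- w / sum(w)
    if (err < 1e-10) break
  }
  list(stumps = stumps, alphas = alphas, features = colnames(X))
}
.ada_margin <- function(model, Xnew, n_rounds = Inf) {
  df <- data.frame(Xnew, check.names = FALSE)
  Fm <- numeric(nrow(Xnew))
  tmax <- min(length(model$stumps), n_rounds)
  for (t in seq_len(tmax)) {
    h <- ifelse(stats::predict(model$stumps[[t]], df,
                               type = "class") == "died", 1, -1)
    Fm <- Fm + model$alphas[t] * h
  }
  Fm
}
.score_ada_boost_bag <- function(model, Xnew)
  stats::plogis(2 * .ada_margin(model, Xnew))
.imp_ada_boost_bag <- function(model) {
  imp <- stats::setNames(numeric(length(model$features)), model$features)
  for (t in seq_along(model$stumps)) {
    fr <- model$stumps[[t]]$frame
    var <- as.character(fr$var[fr$var != "<leaf>"])
    if (length(var)) imp[var[1]] <- imp[var[1]] + model$alphas[t]
  }
  list(importance = imp, native = NULL)
}
.path_ada_boost_bag <- function(X, y01, yf, grid, seed) {
  model <- .fit_ada_boost_bag(X, y01, yf,
                              list(n_rounds = max(grid$n_rounds)), seed)
  function(Xnew) {
    df <- data.frame(Xnew, check.names = FALSE)
    H <- vapply(seq_along(model$stumps), function(t)
      ifelse(stats::predict(model$stumps[[t]], df,
                            type = "class") == "died", 1, -1),
      numeric(nrow(Xnew)))
    if (is.null(dim(H))) H <- matrix(H, nrow = 1L)
    staged <- apply(sweep(H, 2L, model$alphas, `*`), 1L, cumsum)
    staged <- if (is.null(dim(staged))) matrix(staged, nrow = 1L) else t(staged)
    sapply(grid$n_rounds, function(r) {
      tt <- min(r, length(model$alphas))
      if (tt == 0) rep(0.5, nrow(Xnew)) else stats::plogis(2 * staged[, tt])
    })
  }
}

## Penalized logistic regressions (glmnet); lambda expressed relative to the
## per-fit lambda_max so grid points align across folds
.glmnet_lambda_max <- function(X, y01, alpha) {
  yb <- y01 - mean(y01)
  max(abs(crossprod(X, yb))) / (nrow(X) * max(alpha, 1e-3))
}
.fit_glmnet <- function(X, y01, yf, hyper, seed, alpha) {
  lmax <- .glmnet_lambda_max(X, y01, alpha)
  lam <- lmax * hyper$lambda_frac
  # fit a short descending path ending at the target for warm-start stability
  path <- sort(unique(c(lmax, lam * c(4, 2, 1))), decreasing = TRUE)
  fit <- glmnet::glmnet(X, yf, family = "binomial", alpha = alpha,
                        lambda = path, standardize = FALSE)
  list(fit = fit, lambda = lam)
}
.score_glmnet <- function(model, Xnew)
  drop(stats::predict(model$fit, Xnew, s = model$lambda, type = "response",
                      exact = FALSE))
.imp_glmnet <- function(model) {
  b <- drop(stats::coef(model$fit, s = model$lambda))[-1]
  # coefficients sitting numerically on the KKT boundary are zero
  b[abs(b) < 1e-10] <- 0
  list(importance = abs(b), native = b != 0)
}
.path_glmnet <- function(X, y01, yf, grid, seed, alpha) {
  lmax <- .glmnet_lambda_max(X, y01, alpha)
  lam <- lmax * grid$lambda_frac
  fit <- glmnet::glmnet(X, yf, family = "binomial", alpha = alpha,
                        lambda = sort(unique(c(lmax, lam)), decreasing = TRUE),
                        standardize = FALSE)
  function(Xnew) {
    pr <- stats::predict(fit, Xnew, s = lam, type = "response")
    matrix(pr, nrow = nrow(Xnew))
  }
}

.fit_lasso_logistic <- function(X, y01, yf, hyper, seed)
  .fit_glmnet(X, y01, yf, hyper, seed, alpha = 1)
.score_lasso_logistic <- .score_glmnet
.imp_lasso_logistic <- .imp_glmnet
.path_lasso_logistic <- function(X, y01, yf, grid, seed)
  .path_glmnet(X, y01, yf, grid, seed, alpha = 1)

.fit_penalized_logistic <- function(X, y01, yf, hyper, seed)
  .fit_glmnet(X, y01, yf, hyper, seed, alpha = 0.1)
.score_penalized_logistic <- .score_glmnet
.imp_penalized_logistic <- .imp_glmnet
.path_penalized_logistic <- function(X, y01, yf, grid, seed)
  .path_glmnet(X, y01, yf, grid, seed, alpha = 0.1)

# ---- public fit / score / importance ---------------------------------------

.check_hyper <- function(spec, hyper) {
  hyper <- as.list(hyper)
  gcols <- names(spec$grid)
  if (!all(gcols %in% names(hyper)))
    stop("hyperparameters must name: ", paste(gcols, collapse = ", "))
  for (g in gcols)
    if (!hyper[[g]] %in% spec$grid[[g]])
      stop(sprintf("hyperparameter %s = %s outside the grid domain",
                   g, format(hyper[[g]])))
  hyper
}

#' Fit one model family
#'
#' @param spec a [modelSpec()].
#' @param X complete (imputed), scaled samples x metabolites numeric matrix
#'   with column names.
#' @param y binary outcome (0/1 or survived/died factor) with both classes.
#' @param hyperparams named list/row with one value per grid column; values
#'   must come from the grid domain. Defaults to the first grid row.
#' @param seed integer seed (stochastic families are deterministic given it).
#' @return list of class `FittedModel` supporting [scoreModel()] and
#'   [importanceVector()].
#' @export
fitModel <- function(spec, X, y, hyperparams = NULL, seed = 1L) {
  stopifnot(inherits(spec, "ModelSpec"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  yf <- .as_y(y)
  y01 <- as.integer(yf == "died")
  if (is.null(hyperparams)) hyperparams <- as.list(spec$grid[1, , drop = FALSE])
  hyper <- .check_hyper(spec, hyperparams)
  fitter <- get(paste0(".fit_", spec$family_id), mode = "function")
  inner <- fitter(X, y01, yf, hyper, seed)
  structure(list(spec = spec, hyper = hyper, inner = inner,
                 features = colnames(X), seed = seed),
            class = "FittedModel")
}

#' Score samples with a fitted model
#'
#' Scores are oriented so that larger values mean higher predicted death
#' risk, on the probability scale, for every family.
#'
#' @param fitted a [fitModel()] result.
#' @param Xnew samples x metabolites matrix with the training columns.
#' @return numeric vector of death-risk scores in \[0, 1\].
#' @export
scoreModel <- function(fitted, Xnew) {
  stopifnot(inherits(fitted, "FittedModel"))
  Xnew <- as.matrix(Xnew)
  if (is.null(colnames(Xnew))) colnames(Xnew) <- fitted$features
  scorer <- get(paste0(".score_", fitted$spec$family_id), mode = "function")
  unname(scorer(fitted$inner, Xnew))
}

#' Extract the innate importance vector
#'
#' Family-specific nonnegative importances: absolute coefficients for the
#' penalized regressions, VIP scores for PLS-DA, maximum absolute shrunken
#' centroid differences for nearest shrunken centroids, impurity importance
#' for random forests, total boosting weight per splitting feature, the
#' absolute linear weight vector for the SVM, and feature-subset support
#' frequency for random KNN. The selected mask follows the family's
#' `selection_mode` (`native`: the intrinsic sparse support; `top_n`: the
#' `top_n` largest importances, ties broken by metabolite order).
#'
#' @param fitted a [fitModel()] result.
#' @return list of class `ImportanceVector`: `family_id`, `importance`
#'   (named, finite, >= 0), `selected` (named logical), `native` (logical or
#'   `NULL`).
#' @export
importanceVector <- function(fitted) {
  stopifnot(inherits(fitted, "FittedModel"))
  ex <- get(paste0(".imp_", fitted$spec$family_id), mode = "function")
  res <- ex(fitted$inner)
  imp <- res$importance
  imp[!is.finite(imp)] <- 0
  imp <- pmax(imp, 0)
  names(imp) <- fitted$features
  native <- res$native
  if (!is.null(native)) names(native) <- fitted$features
  iv <- structure(list(family_id = fitted$spec$family_id, importance = imp,
                       native = native),
                  class = "ImportanceVector")
  iv$selected <- seq_along(imp) %in%
    match(topSelection(iv, rule = fitted$spec$selection_mode,
                       n = fitted$spec$top_n), names(imp))
  names(iv$selected) <- fitted$features
  iv
}

#' Select the highly ranked metabolites from an importance vector
#'
#' @param iv an [importanceVector()] result.
#' @param rule `"top_n"` (the `n` largest importances, ties broken by the
#'   fixed metabolite order) or `"native"` (the family's intrinsic sparse
#'   support; an error for families without one).
#' @param n cut for `top_n` (default 20); `n >=` feature count returns all.
#' @return character vector of metabolite ids (may be empty for a degenerate
#'   intercept-only fit under `native`).
#' @export
topSelection <- function(iv, rule = c("top_n", "native"), n = 20L) {
  rule <- match.arg(rule)
  imp <- iv$importance
  if (rule == "native") {
    if (is.null(iv$native))
      stop("family '", iv$family_id, "' has no intrinsic sparse selection")
    return(names(imp)[iv$native])
  }
  stopifnot(n >= 1)
  # degenerate all-zero importance: nothing is "ranked highly"
  if (all(imp == 0)) return(character(0))
  ord <- order(-imp, seq_along(imp))
  names(imp)[ord[seq_len(min(n, length(imp)))]]
}

#' @export
print.ImportanceVector <- function(x, ...) {
  cat("ImportanceVector [", x$family_id, "]: ", length(x$importance),
      " features, ", sum(x$selected), " selected\n", sep = "")
  invisible(x)
}
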