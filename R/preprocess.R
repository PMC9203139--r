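#' Preprocessing configuration
#'
#' @param lod_exclusion_fraction metabolites with a below-LOD fraction
#'   *strictly greater* than this are excluded (default 0.10).
#' @param imputation_strategy fill rule for below-LOD cells, computed per
#'   metabolite from observed cells on the current scale:
#'   `"half_min"` (half the minimum observed; default),
#'   `"min"` (the minimum observed), or `"min_over_sqrt2"` (minimum observed
#'   divided by sqrt(2), a detection-limit proxy).
#' @param scaling `"standardize"` (per-metabolite z-score, applied fold-safely
#'   during model tuning) or `"none"`.
#' @return list of class `PreprocessConfig`.
#' @export
preprocessConfig <- function(lod_exclusion_fraction = 0.10,
                             imputation_strategy = c("half_min", "min",
                                                     "min_over_sqrt2"),
                             scaling = c("standardize", "none")) {
  stopifnot(lod_exclusion_fraction >= 0, lod_exclusion_fraction <= 1)
  structure(list(lod_exclusion_fraction = lod_exclusion_fraction,
                 imputation_strategy = match.arg(imputation_strategy),
                 scaling = match.arg(scaling)),
            class = "PreprocessConfig")
}

#' Remove drug metabolites
#'
#' @param x a [MetaboliteExperiment-class] with an `is_drug` annotation.
#' @return list with `experiment` (drug metabolites removed, order otherwise
#'   preserved) and `removed` (character ids).
#' @export
excludeDrugMetabolites <- function(x) {
  stopifnot(methods::is(x, "MetaboliteExperiment"))
  drug <- SummarizedExperiment::rowData(x)$is_drug
  removed <- rownames(x)[drug]
  out <- x[!drug, ]
  if (nrow(out) == 0) warning("all metabolites were drug-flagged")
  list(experiment = out, removed = removed)
}

#' Filter metabolites by below-LOD fraction
#'
#' A metabolite is removed iff its fraction of below-LOD cells is strictly
#' greater than `lod_exclusion_fraction` (the >10% rule under defaults); a
#' metabolite at exactly the threshold is retained. The decision depends only
#' on the mask.
#'
#' @param x a [MetaboliteExperiment-class].
#' @param config a [preprocessConfig()].
#' @return list with `experiment` and `removed` ids.
#' @export
filterBelowLOD <- function(x, config = preprocessConfig()) {
  stopifnot(methods::is(x, "MetaboliteExperiment"))
  frac <- rowMeans(belowLOD(x))
  drop <- frac > config$lod_exclusion_fraction
  list(experiment = x[!drop, ], removed = rownames(x)[drop])
}

#' Log10-transform observed abundances
#'
#' Replaces every observed cell with its base-10 logarithm and flips the scale
#' tag; the below-LOD mask is unchanged. Applying it twice is an error (the
#' scale tag guards against double transformation).
#'
#' @param x a raw-scale [MetaboliteExperiment-class] with positive observed
#'   values.
#' @return the transformed `MetaboliteExperiment` (scale tag `"log10"`).
#' @export
log10Transform <- function(x) {
  stopifnot(methods::is(x, "MetaboliteExperiment"))
  if (abundanceScale(x) != "raw")
    stop("abundance is already on the log10 scale")
  ab <- abundance(x)
  bad <- which(!is.na(ab) & ab <= 0, arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-positive abundance at metabolite %s, sample %s",
                 rownames(ab)[bad[1, 1]], colnames(ab)[bad[1, 2]]))
  SummarizedExperiment::assay(x, "abundance") <- log10(ab)
  S4Vectors::metadata(x)$scale <- "log10"
  x
}

# per-metabolite fill values from observed cells only, on the current scale
.impute_fill <- function(obs, strategy) {
  m <- min(obs)
  switch(strategy,
         half_min = m / 2,
         min = m,
         min_over_sqrt2 = m / sqrt(2))
}

#' Impute below-LOD cells
#'
#' Every masked cell receives a fill value computed per metabolite from that
#' metabolite's observed cells only, on the current scale; observed cells are
#' untouched. The mask is retained as provenance.
#'
#' @param x a [MetaboliteExperiment-class]; every metabolite must have at
#'   least one observed value.
#' @param config a [preprocessConfig()].
#' @return list with `experiment` (no remaining `NA` abundances) and
#'   `imputed_cells` (count).
#' @export
imputeMissing <- function(x, config = preprocessConfig()) {
  stopifnot(methods::is(x, "MetaboliteExperiment"))
  ab <- abundance(x)
  bl <- belowLOD(x)
  n_imputed <- 0L
  for (j in seq_len(nrow(ab))) {
    miss <- bl[j, ] | is.na(ab[j, ])
    if (!any(miss)) next
    obs <- ab[j, !miss]
    if (length(obs) == 0)
      stop(sprintf("metabolite %s has no observed values", rownames(ab)[j]))
    ab[j, miss] <- .impute_fill(obs, config$imputation_strategy)
    n_imputed <- n_imputed + sum(miss)
  }
  SummarizedExperiment::assay(x, "abundance") <- ab
  list(experiment = x, imputed_cells = n_imputed)
}

#' Fold-safe standardization
#'
#' Computes per-feature mean and (sample) standard deviation on the training
#' matrix only and applies the same parameters to the training matrix and any
#' number of held-out matrices, so no information leaks from test folds.
#' Zero-variance training columns are mapped to all-zeros (with a warning)
#' rather than dropped, keeping feature indexing stable across folds.
#'
#' @param train samples x features numeric matrix (>= 2 rows).
#' @param ... further samples x features matrices to transform with the
#'   training parameters.
#' @return list with `train`, `applied` (list of transformed `...` matrices),
#'   `center`, `scale`.
#' @export
standardizeFold <- function(train, ...) {
  train <- as.matrix(train)
  stopifnot(nrow(train) >= 2)
  ctr <- colMeans(train)
  sdv <- apply(train, 2L, stats::sd)
  flat <- !is.finite(sdv) | sdv == 0
  if (any(flat)) {
    warning(sum(flat), " zero-variance training column(s) scaled to zero")
    sdv[flat] <- 1
    ctr[flat] <- train[1, flat]  # maps constant columns (and any test value
  }                              # equal to them) onto zero
  tf <- function(m) sweep(sweep(as.matrix(m), 2L, ctr), 2L, sdv, `/`)
  list(train = tf(train), applied = lapply(list(...), tf),
       center = ctr, scale = sdv)
}

#' Run the full preprocessing chain
#'
#' Fixed stage order: drug-metabolite exclusion, below-LOD filtering
#' (strict greater-than-10% rule), log10 transformation, then imputation of the surviving masked
#' cells on the log10 scale. Set `impute = FALSE` to stop before imputation
#' (model tuning re-imputes fold-safely from training folds only).
#'
#' @param x a raw-scale [MetaboliteExperiment-class].
#' @param config a [preprocessConfig()].
#' @param impute whether to impute after the transform (default `TRUE`).
#' @return list with `experiment` and `report` (class `PreprocessReport`:
#'   per-stage metabolite counts, removed ids per rule, imputed cell count).
#' @export
preprocessCohort <- function(x, config = preprocessConfig(), impute = TRUE) {
  n0 <- nrow(x)
  s1 <- excludeDrugMetabolites(x)
  s2 <- filterBelowLOD(s1$experiment, config)
  s3 <- log10Transform(s2$experiment)
  imputed <- 0L
  if (impute) {
    s4 <- imputeMissing(s3, config)
    s3 <- s4$experiment
    imputed <- s4$imputed_cells
  }
  report <- structure(
    list(n_input_metabolites = n0,
         n_after_drug_exclusion = n0 - length(s1$removed),
         n_after_lod_filter = n0 - length(s1$removed) - length(s2$removed),
         removed_drug = s1$removed,
         removed_lod = s2$removed,
         imputed_cell_count = imputed),
    class = "PreprocessReport")
  list(experiment = s3, report = report)
}

#' @export
print.PreprocessReport <- function(x, ...) {
  cat("Preprocessing report\n")
  cat("  input metabolites:      ", x$n_input_metabolites, "\n")
  cat("  after drug exclusion:   ", x$n_after_drug_exclusion, "\n")
  cat("  after below-LOD filter: ", x$n_after_lod_filter, "\n")
  cat("  imputed cells:          ", x$imputed_cell_count, "\n")
  invisible(x)
}
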