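# deterministic polynomial rolling hash of a serialized R object
# (config fingerprinting; double arithmetic stays exact below 2^53)
.config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^32
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Pipeline configuration
#'
#' Exactly one of `synthetic` (a [syntheticConfig()]) or `input_paths` (named
#' list with `matrix`, `annotations`, `metadata`) must be supplied.
#'
#' @param synthetic a [syntheticConfig()] to generate the cohort, or `NULL`.
#' @param input_paths named list of delimited-text input paths, or `NULL`.
#' @param preprocess a [preprocessConfig()].
#' @param n_folds,n_repeats cross-validation design (defaults 5 and 50).
#' @param families registry subset (default: all eight families).
#' @param top_n "ranked highly" cut for non-sparse families (default 20).
#' @param score_threshold ensemble prioritization threshold (default 0.5).
#' @param classification_threshold probability cut for sensitivity /
#'   specificity reporting (default 0.5).
#' @param seed master seed (mandatory; all stage substreams derive from it).
#' @param verbose emit stage progress messages.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(synthetic = syntheticConfig(),
                           input_paths = NULL,
                           preprocess = preprocessConfig(),
                           n_folds = 5L, n_repeats = 50L,
                           families = NULL, top_n = 20L,
                           score_threshold = 0.5,
                           classification_threshold = 0.5,
                           seed = 1L, verbose = FALSE) {
  if (is.null(synthetic) == is.null(input_paths))
    stop("exactly one of 'synthetic' or 'input_paths' must be set")
  structure(list(synthetic = synthetic, input_paths = input_paths,
                 preprocess = preprocess, n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats), families = families,
                 top_n = as.integer(top_n), score_threshold = score_threshold,
                 classification_threshold = classification_threshold,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "PipelineConfig")
}

#' Run the full consensus-ranking pipeline
#'
#' Stages: cohort acquisition (synthetic generation or file input),
#' preprocessing (drug exclusion, strict >10% below-LOD filter, log10),
#' repeated stratified cross-validation tuning of every registry family
#' under the PR curve (fold-safe imputation and scaling), full-data refits
#' and innate importance extraction, the selection matrix and ensemble
#' importance scores, cross-model agreement, the univariate screen, the PCA
#' variance profile and hierarchical clustering orders. Deterministic given
#' the seed.
#'
#' @param config a [pipelineConfig()].
#' @return list of class `ReportBundle` with elements `experiment`,
#'   `preprocess_report`, `model_results`, `performance`, `selection_matrix`,
#'   `ranking`, `consensus_table`, `prioritized`, `agreement`, `univariate`,
#'   `variance_profile`, `heatmap`, `truth` (synthetic runs only) and
#'   `manifest`.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  vb <- config$verbose
  t0 <- Sys.time()

  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    syn$seed <- .substream(config$seed, 1L)
    .msg(vb, "stage cohort: generating synthetic cohort (seed ", syn$seed, ")")
    cohort <- generateCohort(syn)
    me0 <- cohort$experiment
    truth <- cohort$truth
  } else {
    .msg(vb, "stage cohort: reading input files")
    me0 <- readMetaboliteExperiment(config$input_paths$matrix,
                                    config$input_paths$annotations,
                                    config$input_paths$metadata)
    truth <- NULL
  }
  yf <- .as_y(sampleOutcome(me0))

  .msg(vb, "stage preprocess: ", nrow(me0), " input metabolites")
  pp <- preprocessCohort(me0, config$preprocess, impute = FALSE)
  me <- pp$experiment
  .msg(vb, "stage preprocess: ", nrow(me), " metabolites retained")

  plan <- makeFoldPlan(yf, n_folds = config$n_folds,
                       n_repeats = config$n_repeats, stratified = TRUE,
                       seed = .substream(config$seed, 2L))

  registry <- defaultRegistry(config$families, top_n = config$top_n)
  results <- vector("list", length(registry))
  names(results) <- names(registry)
  for (i in seq_along(registry)) {
    fam <- names(registry)[i]
    .msg(vb, "stage fit: tuning ", fam)
    results[[i]] <- tuneModel(
      registry[[i]], me, yf, plan,
      threshold = config$classification_threshold,
      imputation_strategy = config$preprocess$imputation_strategy,
      seed = .substream(config$seed, 200L + i))
  }

  performance <- do.call(rbind, lapply(results, function(r)
    data.frame(family = r$family_id,
               pr_auc_mean = r$summary["mean", "pr_auc"],
               pr_auc_sd = r$summary["sd", "pr_auc"],
               roc_auc_mean = r$summary["mean", "roc_auc"],
               sensitivity_mean = r$summary["mean", "sensitivity"],
               specificity_mean = r$summary["mean", "specificity"],
               n_selected = length(r$selection),
               stringsAsFactors = FALSE)))
  rownames(performance) <- NULL

  .msg(vb, "stage rank: building consensus")
  sel <- buildSelectionMatrix(lapply(results, `[[`, "selection"),
                              rownames(me))
  ranking <- ensembleImportance(sel)
  prioritized <- applyThreshold(ranking, config$score_threshold)

  # full-data imputation for descriptive statistics and figures
  imp <- imputeMissing(me, config$preprocess)$experiment
  uni <- univariateScreen(imp, yf)
  # consensus table in the style of the study's top-metabolite table:
  # score, raw-scale group medians (IQR), univariate p
  raw_imp <- imp
  SummarizedExperiment::assay(raw_imp, "abundance") <- 10^abundance(imp)
  uni_raw <- univariateScreen(raw_imp, yf)
  consensus <- merge(ranking, uni_raw, by = "metabolite", sort = FALSE)
  consensus <- consensus[order(consensus$rank), ]
  consensus$prioritized <- consensus$score >= config$score_threshold
  rownames(consensus) <- NULL

  agreement <- pairwiseAgreement(sel)
  vp <- pcaVarianceProfile(assayMatrix(imp), standardize = TRUE)

  hm <- suppressWarnings(standardizeFold(assayMatrix(imp)))$train
  heat <- list(matrix = t(hm),
               metabolite_order = hierarchicalClusterOrder(t(hm)),
               sample_order = hierarchicalClusterOrder(hm))

  manifest <- list(package_version = as.character(
                     utils::packageVersion("metaboConsensus")),
                   seed = config$seed,
                   config_hash = .config_hash(unclass(config)),
                   n_samples = ncol(me), n_metabolites_input = nrow(me0),
                   n_metabolites_analyzed = nrow(me),
                   n_models = length(registry),
                   elapsed_sec = as.numeric(difftime(Sys.time(), t0,
                                                     units = "secs")))

  structure(list(experiment = me, preprocess_report = pp$report,
                 model_results = results, performance = performance,
                 selection_matrix = sel, ranking = ranking,
                 consensus_table = consensus, prioritized = prioritized,
                 agreement = agreement, univariate = uni,
                 variance_profile = vp, heatmap = heat, truth = truth,
                 manifest = manifest),
            class = "ReportBundle")
}

.fmt_num <- function(df) {
  isnum <- vapply(df, is.numeric, logical(1))
  df[isnum] <- lapply(df[isnum], function(v) signif(v, 6))
  df
}

#' Write a report bundle as delimited text files
#'
#' One UTF-8 CSV per table with a header row and deterministic column order;
#' floating point values are printed at 6 significant digits for
#' diffability. The run manifest (config hash, seed, versions, counts) is
#' written as JSON.
#'
#' @param bundle a [runPipeline()] result.
#' @param outdir output directory.
#' @param overwrite allow writing into an existing non-empty directory
#'   (default `FALSE`).
#' @return invisibly, the vector of written file paths.
#' @export
writeReportBundle <- function(bundle, outdir, overwrite = FALSE) {
  stopifnot(inherits(bundle, "ReportBundle"))
  if (dir.exists(outdir) && length(list.files(outdir)) && !overwrite)
    stop("output directory exists and is not empty; set overwrite = TRUE")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.csv(.fmt_num(df), path, row.names = FALSE)
    path
  }
  rep <- bundle$preprocess_report
  paths <- c(
    w(data.frame(stage = c("input", "after_drug_exclusion",
                           "after_lod_filter"),
                 n_metabolites = c(rep$n_input_metabolites,
                                   rep$n_after_drug_exclusion,
                                   rep$n_after_lod_filter)),
      "preprocess_report.csv"),
    w(bundle$performance, "performance.csv"),
    w(bundle$consensus_table, "consensus_table.csv"),
    w(data.frame(model = rownames(bundle$agreement$jaccard),
                 as.data.frame(bundle$agreement$jaccard)),
      "agreement_jaccard.csv"),
    w(bundle$univariate, "univariate.csv"),
    w(data.frame(component = seq_along(bundle$variance_profile$fraction),
                 fraction = bundle$variance_profile$fraction,
                 cumulative = bundle$variance_profile$cumulative),
      "variance_profile.csv"),
    w(data.frame(metabolite_id = rownames(bundle$heatmap$matrix)[
        bundle$heatmap$metabolite_order]), "heatmap_metabolite_order.csv"),
    w(data.frame(sample_id = colnames(bundle$heatmap$matrix)[
        bundle$heatmap$sample_order]), "heatmap_sample_order.csv"),
    w(data.frame(metabolite_id = rownames(bundle$heatmap$matrix),
                 .fmt_num(as.data.frame(bundle$heatmap$matrix))),
      "heatmap_matrix.csv"))
  mp <- file.path(outdir, "manifest.json")
  jsonlite::write_json(bundle$manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mp))
}

#' @export
print.ReportBundle <- function(x, ...) {
  cat("ReportBundle:", x$manifest$n_metabolites_analyzed,
      "metabolites analyzed across", x$manifest$n_models, "model families\n")
  cat("  prioritized metabolites (score >= threshold):",
      nrow(x$prioritized), "\n")
  invisible(x)
}
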