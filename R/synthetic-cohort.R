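#' Configuration for the synthetic sepsis-metabolome cohort generator
#'
#' Defaults mirror the structure of the motivating study cohort: 60 ICU
#' patients, 411 profiled metabolites across 8 Metabolon-style super-pathways,
#' a 28-day mortality rate of 0.42, right-skewed (log-normal) ion-count
#' abundances with exchangeable within-pathway correlation, left-censoring at
#' a per-metabolite limit of detection, and 13 metabolites carrying a planted
#' mortality-linked shift (non-survivors higher).
#'
#' @param n_samples number of samples (default 60).
#' @param n_metabolites number of raw metabolites (default 411).
#' @param n_pathways number of super-pathways (default 8).
#' @param within_pathway_correlation exchangeable correlation within a
#'   super-pathway block, in `[0, 1)` (default 0.4).
#' @param n_effect_metabolites number of metabolites with a planted
#'   outcome-linked shift (default 13).
#' @param effect_size standardized mean difference (died minus survived) on
#'   the log10 scale for planted metabolites (default 1.0).
#' @param target_event_rate probability of 28-day death (default 0.42).
#' @param lod_quantile_range length-2 numeric in `[0, 1)`: per-metabolite
#'   censoring severity (the quantile at which the detection limit sits) is
#'   drawn uniformly from this range. The default `c(0, 0.3)` makes roughly
#'   60% of metabolites fail a strict >10% below-LOD filter, emulating the
#'   411 -> ~160 quality-control attrition.
#' @param drug_metabolite_fraction fraction of metabolites flagged as drug
#'   metabolites (default 0.05); drug flags never land on planted metabolites.
#' @param exact_event_counts if `TRUE` (default) the realized number of deaths
#'   is exactly `round(n_samples * target_event_rate)`.
#' @param seed master integer seed; per-stage substreams are derived from it.
#' @return A validated list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(n_samples = 60L,
                            n_metabolites = 411L,
                            n_pathways = 8L,
                            within_pathway_correlation = 0.4,
                            n_effect_metabolites = 13L,
                            effect_size = 1.0,
                            target_event_rate = 0.42,
                            lod_quantile_range = c(0, 0.3),
                            drug_metabolite_fraction = 0.05,
                            exact_event_counts = TRUE,
                            seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_metabolites = as.integer(n_metabolites),
              n_pathways = as.integer(n_pathways),
              within_pathway_correlation = within_pathway_correlation,
              n_effect_metabolites = as.integer(n_effect_metabolites),
              effect_size = effect_size,
              target_event_rate = target_event_rate,
              lod_quantile_range = lod_quantile_range,
              drug_metabolite_fraction = drug_metabolite_fraction,
              exact_event_counts = isTRUE(exact_event_counts),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_samples > 0, n_metabolites > 0, n_pathways > 0)
    if (n_effect_metabolites > n_metabolites)
      stop("n_effect_metabolites exceeds n_metabolites")
    if (!(target_event_rate > 0 && target_event_rate < 1))
      stop("target_event_rate must lie in (0, 1)")
    if (within_pathway_correlation < 0 || within_pathway_correlation >= 1)
      stop("within_pathway_correlation must lie in [0, 1)")
    if (length(lod_quantile_range) != 2 ||
        any(lod_quantile_range < 0) || any(lod_quantile_range >= 1))
      stop("lod_quantile_range must be two probabilities in [0, 1)")
  })
  structure(cfg, class = "SyntheticConfig")
}

.SUPER_PATHWAYS <- c("Amino acid", "Lipid", "Carbohydrate", "Nucleotide",
                     "Peptide", "Cofactors and vitamins", "Energy",
                     "Xenobiotics")
# rough Metabolon panel composition; recycled/renormalized for other n_pathways
.PATHWAY_WEIGHTS <- c(0.30, 0.33, 0.08, 0.06, 0.06, 0.07, 0.04, 0.06)

#' Generate a synthetic cohort with ground truth
#'
#' Draws block-correlated latent Gaussians (exchangeable correlation within
#' each super-pathway), plants an outcome-linked shift of `effect_size`
#' standard deviations on the latent (log10) scale for the effect metabolites,
#' exponentiates base 10 to obtain strictly positive ion-count-scale
#' abundances, and left-censors each metabolite at a detection limit drawn
#' from `lod_quantile_range`. The outcome and latents jointly follow a
#' linear-logistic model: the class-conditional Gaussian construction used
#' here has posterior log-odds `b + beta' z` with slope `beta = solve(Sigma,
#' delta)` and intercept `b = logit(rate) - delta' solve(Sigma, delta) / 2`,
#' which is recorded in the truth manifest.
#'
#' @param config a [syntheticConfig()] object.
#' @return A list of class `SyntheticCohort` with elements
#'   `experiment` (a [MetaboliteExperiment-class], raw scale, censored) and
#'   `truth` (class `SyntheticTruth`: `effects` data.frame of
#'   `metabolite_id`/`effect_size`, and `outcome_model_intercept`).
#' @export
generateCohort <- function(config = syntheticConfig()) {
  stopifnot(inherits(config, "SyntheticConfig"))
  n <- config$n_samples; p <- config$n_metabolites
  r <- config$within_pathway_correlation
  met_ids <- sprintf("M%04d", seq_len(p))
  smp_ids <- sprintf("S%03d", seq_len(n))

  # pathway / annotation assignment
  w <- rep_len(.PATHWAY_WEIGHTS, config$n_pathways)
  w <- w / sum(w)
  paths <- rep_len(.SUPER_PATHWAYS, config$n_pathways)
  pathway <- .with_seed(.substream(config$seed, 11L),
                        sample(paths, p, replace = TRUE, prob = w))
  sub_pathway <- .with_seed(.substream(config$seed, 12L),
                            paste(pathway, "/ sub-pathway",
                                  sample.int(3L, p, replace = TRUE)))

  planted <- if (config$n_effect_metabolites > 0)
    .with_seed(.substream(config$seed, 13L),
               sort(sample.int(p, config$n_effect_metabolites)))
  else integer()

  n_drug <- round(config$drug_metabolite_fraction * p)
  candidates <- setdiff(seq_len(p), planted)
  is_drug <- rep(FALSE, p)
  if (n_drug > 0 && length(candidates))
    is_drug[.with_seed(.substream(config$seed, 14L),
                       sample(candidates, min(n_drug, length(candidates))))] <- TRUE

  # per-metabolite location/scale on the log10 ion-count scale
  mu <- .with_seed(.substream(config$seed, 15L), runif(p, 4.5, 8.0))
  sigma <- .with_seed(.substream(config$seed, 16L), runif(p, 0.25, 0.6))

  # outcome
  k_events <- round(n * config$target_event_rate)
  y <- if (config$exact_event_counts) {
    idx <- .with_seed(.substream(config$seed, 17L), sample.int(n, k_events))
    as.integer(seq_len(n) %in% idx)
  } else {
    .with_seed(.substream(config$seed, 17L),
               rbinom(n, 1L, config$target_event_rate))
  }

  # block-correlated latents with planted class shift
  block <- match(pathway, paths)
  z <- .with_seed(.substream(config$seed, 18L), {
    f <- matrix(rnorm(n * config$n_pathways), n, config$n_pathways)
    e <- matrix(rnorm(n * p), n, p)
    sqrt(r) * f[, block, drop = FALSE] + sqrt(1 - r) * e
  })
  delta <- numeric(p)
  delta[planted] <- config$effect_size
  z <- z + outer(y, delta)

  x_raw <- 10^(sweep(sweep(z, 2L, sigma, `*`), 2L, mu, `+`))
  dimnames(x_raw) <- list(smp_ids, met_ids)

  # implied logistic intercept: b = logit(pi) - delta' Sigma^-1 delta / 2,
  # with Sigma block-exchangeable so Sigma^-1 delta has a closed form.
  v <- 0
  if (length(planted)) {
    for (b in unique(block[planted])) {
      in_b <- planted[block[planted] == b]
      m_b <- sum(block == b)
      d_b <- delta[in_b]
      cc <- r * sum(d_b) / (1 + (m_b - 1) * r)
      v <- v + sum(d_b * (d_b - cc)) / (1 - r)
    }
  }
  intercept <- stats::qlogis(config$target_event_rate) - v / 2

  # simple clinical covariates for descriptive statistics
  covars <- .with_seed(.substream(config$seed, 19L), {
    data.frame(
      age = pmin(95, pmax(18, round(rnorm(n, 56 + 4 * y, 12)))),
      female = rbinom(n, 1L, 0.45),
      sofa = pmax(0L, rpois(n, lambda = 8 + 3 * y)))
  })

  me <- MetaboliteExperiment(
    abundance = t(x_raw),
    rowData = data.frame(metabolite = paste0("metabolite-", met_ids),
                         super_pathway = pathway,
                         sub_pathway = sub_pathway,
                         is_drug = is_drug,
                         row.names = met_ids),
    colData = data.frame(outcome = ifelse(y == 1, "died", "survived"),
                         covars, row.names = smp_ids),
    scale = "raw")

  # censoring severity: planted metabolites stay comfortably above the strict
  # >10% exclusion rule (floor(n*q) flagged cells with q <= 0.08); the rest
  # span lod_quantile_range; a zero range disables censoring entirely
  q <- .with_seed(.substream(config$seed, 20L), {
    qq <- runif(p, config$lod_quantile_range[1], config$lod_quantile_range[2])
    if (length(planted))
      qq[planted] <- runif(length(planted), 0,
                           min(0.08, config$lod_quantile_range[2]))
    qq
  })
  me <- censorBelowLOD(me, q)
  SummarizedExperiment::rowData(me)$lod_quantile <- q

  truth <- structure(
    list(effects = data.frame(metabolite_id = met_ids[planted],
                              effect_size = rep(config$effect_size,
                                                length(planted)),
                              stringsAsFactors = FALSE),
         outcome_model_intercept = intercept),
    class = "SyntheticTruth")
  structure(list(experiment = me, truth = truth, config = config),
            class = "SyntheticCohort")
}

#' Left-censor a raw-scale abundance table at per-metabolite detection limits
#'
#' For metabolite `j` with censoring quantile `q_j`, the detection limit is
#' the `(floor(n * q_j) + 1)`-th smallest observed value; all cells strictly
#' below it are flagged below-LOD and their abundance set to `NA`. With
#' distinct values exactly `floor(n * q_j)` cells are flagged. Already-flagged
#' cells stay flagged; all other cells are untouched.
#'
#' @param x a raw-scale [MetaboliteExperiment-class].
#' @param quantileLevels scalar or per-metabolite numeric vector in `[0, 1)`.
#' @return The censored `MetaboliteExperiment`.
#' @export
censorBelowLOD <- function(x, quantileLevels) {
  stopifnot(methods::is(x, "MetaboliteExperiment"))
  if (any(quantileLevels >= 1) || any(quantileLevels < 0))
    stop("quantile levels must lie in [0, 1)")
  q <- rep_len(quantileLevels, nrow(x))
  ab <- abundance(x)
  bl <- belowLOD(x)
  n <- ncol(ab)
  for (j in seq_len(nrow(ab))) {
    k <- floor(q[j] * n)
    if (k < 1) next
    vals <- ab[j, ]
    obs <- sort(vals[!is.na(vals)])
    if (length(obs) <= k) next
    lod <- obs[k + 1L]
    hit <- !is.na(vals) & vals < lod
    bl[j, hit] <- TRUE
    ab[j, hit] <- NA_real_
  }
  SummarizedExperiment::assay(x, "abundance") <- ab
  SummarizedExperiment::assay(x, "belowLOD") <- bl
  methods::validObject(x)
  x
}

#' Calibrate a logistic intercept to hit a target event rate
#'
#' Finds, by bisection, the intercept `b` such that
#' `mean(plogis(b + linear_predictors))` equals `target_rate` to within 1e-10.
#'
#' @param linear_predictors finite numeric vector.
#' @param target_rate probability in (0, 1).
#' @return The intercept (scalar).
#' @export
calibrateOutcomeIntercept <- function(linear_predictors, target_rate) {
  if (!all(is.finite(linear_predictors)))
    stop("linear predictors must be finite")
  if (!(target_rate > 0 && target_rate < 1))
    stop("target_rate must lie in (0, 1)")
  f <- function(b) mean(stats::plogis(b + linear_predictors)) - target_rate
  lo <- -50; hi <- 50
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-12) break
  }
  (lo + hi) / 2
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat("SyntheticCohort:", ncol(x$experiment), "samples x",
      nrow(x$experiment), "metabolites;",
      nrow(x$truth$effects), "planted effect metabolites\n")
  invisible(x)
}
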