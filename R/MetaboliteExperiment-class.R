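#' MetaboliteExperiment: a samples x metabolites abundance container
#'
#' An S4 class extending [SummarizedExperiment::SummarizedExperiment] that
#' holds a metabolite abundance matrix (metabolites as rows, samples as
#' columns, following Bioconductor convention) together with a per-cell
#' below-limit-of-detection mask, per-metabolite annotations and per-sample
#' metadata.
#'
#' Assays:
#' \describe{
#'   \item{`abundance`}{numeric; ion-count-scale (raw) or log10 values,
#'     tracked by the `scale` tag in `metadata()`. Cells flagged below the
#'     detection limit are `NA` until imputed.}
#'   \item{`belowLOD`}{logical; `TRUE` where the measurement fell below the
#'     metabolite's lower detection limit (left-censored).}
#' }
#'
#' Required `rowData` columns: `metabolite` (display name), `super_pathway`,
#' `sub_pathway`, `is_drug` (logical). Required `colData` column: `outcome`,
#' a factor with levels `c("survived", "died")`.
#'
#' @slot .. inherits all slots from `SummarizedExperiment`.
#' @aliases MetaboliteExperiment-class
#' @export
setClass("MetaboliteExperiment",
         contains = "SummarizedExperiment")

.ME_SCALES <- c("raw", "log10")

setValidity("MetaboliteExperiment", function(object) {
  msgs <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("abundance", "belowLOD") %in% an))
    msgs <- c(msgs, "assays 'abundance' and 'belowLOD' are required")
  else {
    ab <- SummarizedExperiment::assay(object, "abundance")
    bl <- SummarizedExperiment::assay(object, "belowLOD")
    if (!identical(dim(ab), dim(bl)))
      msgs <- c(msgs, "'abundance' and 'belowLOD' dimensions disagree")
    if (!is.logical(bl))
      msgs <- c(msgs, "'belowLOD' assay must be logical")
    sc <- S4Vectors::metadata(object)$scale
    if (is.null(sc) || !sc %in% .ME_SCALES)
      msgs <- c(msgs, "metadata scale tag must be 'raw' or 'log10'")
    else if (identical(sc, "raw")) {
      obs <- ab[!bl & !is.na(ab)]
      if (length(obs) && any(obs <= 0))
        msgs <- c(msgs, "raw-scale observed abundances must be strictly positive")
    }
  }
  rd <- SummarizedExperiment::rowData(object)
  need <- c("metabolite", "super_pathway", "sub_pathway", "is_drug")
  if (!all(need %in% colnames(rd)))
    msgs <- c(msgs, paste("rowData must contain:", paste(need, collapse = ", ")))
  if (anyDuplicated(rownames(object)))
    msgs <- c(msgs, "duplicate metabolite ids")
  if (anyDuplicated(colnames(object)))
    msgs <- c(msgs, "duplicate sample ids")
  if (length(msgs)) msgs else TRUE
})

#' Construct a MetaboliteExperiment
#'
#' @param abundance numeric matrix, metabolites x samples; masked cells `NA`.
#' @param belowLOD logical matrix of the same dimensions (default all `FALSE`).
#' @param rowData `DataFrame`/data.frame of metabolite annotations with columns
#'   `metabolite`, `super_pathway`, `sub_pathway`, `is_drug`.
#' @param colData `DataFrame`/data.frame of sample metadata; an `outcome`
#'   column, when present, is coerced to a `survived`/`died` factor.
#' @param scale `"raw"` or `"log10"`.
#' @return A [MetaboliteExperiment-class] object.
#' @export
MetaboliteExperiment <- function(abundance, belowLOD = NULL, rowData, colData,
                                 scale = "raw") {
  scale <- match.arg(scale, .ME_SCALES)
  abundance <- as.matrix(abundance)
  if (is.null(belowLOD))
    belowLOD <- matrix(FALSE, nrow(abundance), ncol(abundance),
                       dimnames = dimnames(abundance))
  colData <- S4Vectors::DataFrame(colData)
  if ("outcome" %in% colnames(colData))
    colData$outcome <- .as_outcome(colData$outcome)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = abundance, belowLOD = belowLOD),
    rowData = S4Vectors::DataFrame(rowData),
    colData = colData)
  S4Vectors::metadata(se)$scale <- scale
  methods::new("MetaboliteExperiment", se)
}

.as_outcome <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) stop("numeric outcome must be coded 0/1")
    x <- ifelse(x == 1, "died", "survived")
  }
  x <- tolower(as.character(x))
  if (!all(x %in% c("survived", "died")))
    stop("outcome values must be {0,1} or {survived, died}")
  factor(x, levels = c("survived", "died"))
}

#' @describeIn MetaboliteExperiment-accessors abundance matrix (metabolites x samples)
#' @export
abundance <- function(x) SummarizedExperiment::assay(x, "abundance")

#' @describeIn MetaboliteExperiment-accessors below-LOD logical mask
#' @export
belowLOD <- function(x) SummarizedExperiment::assay(x, "belowLOD")

#' Accessors for MetaboliteExperiment
#'
#' @param x a [MetaboliteExperiment-class].
#' @name MetaboliteExperiment-accessors
#' @return `abundance()`/`belowLOD()` the assay matrices; `abundanceScale()`
#'   the scale tag; `sampleOutcome()` the outcome factor; `assayMatrix()` the
#'   abundance matrix transposed to samples x metabolites (model orientation).
NULL

#' @describeIn MetaboliteExperiment-accessors scale tag ("raw" or "log10")
#' @export
abundanceScale <- function(x) S4Vectors::metadata(x)$scale

#' @describeIn MetaboliteExperiment-accessors outcome factor (survived/died)
#' @export
sampleOutcome <- function(x) SummarizedExperiment::colData(x)$outcome

#' @describeIn MetaboliteExperiment-accessors samples x metabolites matrix
#' @export
assayMatrix <- function(x) t(abundance(x))

setMethod("show", "MetaboliteExperiment", function(object) {
  cat("MetaboliteExperiment:", nrow(object), "metabolites x",
      ncol(object), "samples\n")
  cat("  scale:", abundanceScale(object), "\n")
  bl <- belowLOD(object)
  cat(sprintf("  below-LOD cells: %d (%.1f%%)\n", sum(bl),
              100 * mean(bl)))
  rd <- SummarizedExperiment::rowData(object)
  cat("  super-pathways:", length(unique(rd$super_pathway)),
      "| drug metabolites:", sum(rd$is_drug), "\n")
  oc <- SummarizedExperiment::colData(object)$outcome
  if (!is.null(oc))
    cat("  outcome: ", sum(oc == "died"), " died / ", length(oc),
        " samples\n", sep = "")
  invisible(NULL)
})
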