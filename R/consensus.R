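#' Build the models x metabolites selection indicator matrix
#'
#' @param selections named list (one element per model) of character vectors
#'   of selected metabolite ids; duplicates within a set are collapsed and
#'   empty selections give an all-`FALSE` row.
#' @param metabolite_universe character vector of all candidate metabolite
#'   ids (the post-filter universe).
#' @return logical matrix (models x metabolites) of class `SelectionMatrix`.
#' @export
buildSelectionMatrix <- function(selections, metabolite_universe) {
  stopifnot(length(metabolite_universe) > 0,
            !anyDuplicated(metabolite_universe))
  if (is.null(names(selections)) || anyDuplicated(names(selections)))
    stop("selections must be a uniquely named list (one element per model)")
  out <- setdiff(unique(unlist(selections)), metabolite_universe)
  if (length(out))
    stop("selected ids outside the metabolite universe: ",
         paste(utils::head(out, 5), collapse = ", "))
  m <- t(vapply(selections, function(s) metabolite_universe %in% s,
                logical(length(metabolite_universe))))
  dimnames(m) <- list(names(selections), metabolite_universe)
  class(m) <- c("SelectionMatrix", class(m))
  m
}

#' Ensemble importance scores
#'
#' The ensemble importance score of metabolite `j` is the fraction of model
#' families that selected / ranked it highly: `score_j = n_models_selecting /
#' M`. Every score lies on the lattice `{0, 1/M, ..., 1}`; with the default
#' eight-family registry the attainable values include 0.875, 0.75, 0.625 and
#' 0.5. Models with empty selections still count in the denominator.
#'
#' @param matrix a [buildSelectionMatrix()] result (M x P logical).
#' @return data.frame of class `EnsembleRanking`, one row per metabolite:
#'   `metabolite`, `n_models_selecting`, `score` (exact multiple of 1/M),
#'   `rank` (contiguous from 1 after [rankMetabolites()] ordering), with the
#'   model count `M` as an attribute.
#' @export
ensembleImportance <- function(matrix) {
  M <- nrow(matrix)
  stopifnot(M >= 1)
  n_sel <- colSums(matrix)
  rk <- data.frame(metabolite = colnames(matrix),
                   n_models_selecting = as.integer(n_sel),
                   score = as.numeric(n_sel) / M,
                   stringsAsFactors = FALSE)
  rk <- rankMetabolites(rk)
  attr(rk, "n_models") <- M
  class(rk) <- c("EnsembleRanking", "data.frame")
  rk
}

#' Order metabolites by ensemble score
#'
#' Descending by score; within equal scores, ascending alphabetically by
#' metabolite id (the convention of the motivating consensus table). Ranks
#' are contiguous from 1, stable and deterministic.
#'
#' @param ranking an [ensembleImportance()] data.frame (or any data.frame
#'   with `metabolite` and `score` columns).
#' @return the ranking reordered with a `rank` column.
#' @export
rankMetabolites <- function(ranking) {
  o <- order(-ranking$score, ranking$metabolite)
  ranking <- ranking[o, , drop = FALSE]
  ranking$rank <- seq_len(nrow(ranking))
  rownames(ranking) <- NULL
  ranking
}

#' Apply the prioritization threshold
#'
#' Retains metabolites with `score >= threshold` (inclusive: a metabolite at
#' exactly the threshold is prioritized, matching the `>= 0.5` rule).
#'
#' @param ranking an [ensembleImportance()] result.
#' @param threshold tau in \[0, 1\] (default 0.5).
#' @return the prioritized subset, ordered as ranked.
#' @export
applyThreshold <- function(ranking, threshold = 0.5) {
  ranking[ranking$score >= threshold, , drop = FALSE]
}

#' Pairwise agreement between model selections
#'
#' @param matrix a [buildSelectionMatrix()] result.
#' @return list with `intersection` (M x M counts) and `jaccard` (M x M;
#'   two empty selections have Jaccard 1). Both symmetric with unit/diagonal
#'   self-agreement.
#' @export
pairwiseAgreement <- function(matrix) {
  M <- nrow(matrix)
  stopifnot(M >= 2)
  inter <- matrix %*% t(matrix)
  sizes <- rowSums(matrix)
  uni <- outer(sizes, sizes, `+`) - inter
  jac <- ifelse(uni == 0, 1, inter / uni)
  storage.mode(inter) <- "integer"
  list(intersection = inter, jaccard = jac)
}
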