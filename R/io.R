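.detect_sep <- function(path) {
  l1 <- readLines(path, n = 1L)
  if (lengths(regmatches(l1, gregexpr("\t", l1))) > 0) "\t" else ","
}

.read_table <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- .detect_sep(path)
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = NULL, quote = "\"")
}

#' Read a metabolite experiment from delimited text files
#'
#' @param matrix_path CSV/TSV with samples as rows; first column `sample_id`,
#'   remaining columns metabolite abundances. Below-LOD / missing cells are
#'   encoded as empty strings or any of the `sentinels`.
#' @param annotation_path CSV/TSV keyed by `metabolite_id` with columns
#'   `metabolite`, `super_pathway`, `sub_pathway`, `is_drug`.
#' @param metadata_path CSV/TSV keyed by `sample_id` with an `outcome` column
#'   (`0`/`1` or `survived`/`died`) plus optional covariates.
#' @param sentinels cell values treated as below-LOD (default `""`, `"NA"`,
#'   `"<LOD"`).
#' @param sep field delimiter; autodetected (comma vs tab) when `NULL`.
#' @param scale scale tag of the stored abundances (default `"raw"`).
#' @return a [MetaboliteExperiment-class].
#' @export
readMetaboliteExperiment <- function(matrix_path, annotation_path,
                                     metadata_path,
                                     sentinels = c("", "NA", "<LOD"),
                                     sep = NULL, scale = "raw") {
  mt <- .read_table(matrix_path, sep)
  an <- .read_table(annotation_path, sep)
  md <- .read_table(metadata_path, sep)
  if (colnames(mt)[1] != "sample_id") stop("matrix first column must be sample_id")
  if (!"metabolite_id" %in% colnames(an)) stop("annotations need metabolite_id")
  if (!"sample_id" %in% colnames(md)) stop("metadata needs sample_id")
  if (!"outcome" %in% colnames(md)) stop("metadata needs an outcome column")

  sids <- mt$sample_id
  mids <- colnames(mt)[-1]
  if (anyDuplicated(sids)) stop("duplicate sample ids in matrix")
  if (anyDuplicated(mids)) stop("duplicate metabolite ids in matrix")
  missing_md <- setdiff(sids, md$sample_id)
  if (length(missing_md))
    stop("metadata missing sample id(s): ", paste(missing_md, collapse = ", "))
  extra_md <- setdiff(md$sample_id, sids)
  if (length(extra_md))
    stop("metadata has unmatched sample id(s): ",
         paste(extra_md, collapse = ", "))
  missing_an <- setdiff(mids, an$metabolite_id)
  if (length(missing_an))
    stop("annotations missing metabolite id(s): ",
         paste(missing_an, collapse = ", "))

  raw <- as.matrix(mt[, -1, drop = FALSE])
  mask <- matrix(raw %in% sentinels, nrow(raw), ncol(raw))
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  bad <- which(!mask & is.na(vals), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric abundance cell at sample %s, metabolite %s",
                 sids[bad[1, 1]], mids[bad[1, 2]]))
  vals[mask] <- NA_real_
  dimnames(vals) <- list(sids, mids)

  an <- an[match(mids, an$metabolite_id), , drop = FALSE]
  md <- md[match(sids, md$sample_id), , drop = FALSE]
  rowdat <- data.frame(metabolite = an$metabolite,
                       super_pathway = an$super_pathway,
                       sub_pathway = an$sub_pathway,
                       is_drug = as.logical(toupper(an$is_drug) %in%
                                              c("TRUE", "1", "T", "YES")),
                       row.names = mids)
  coldat <- md[, setdiff(colnames(md), "sample_id"), drop = FALSE]
  num_ok <- vapply(coldat, function(v)
    !any(is.na(suppressWarnings(as.numeric(v[v != ""])))), logical(1))
  coldat[num_ok & colnames(coldat) != "outcome"] <-
    lapply(coldat[num_ok & colnames(coldat) != "outcome"], as.numeric)
  rownames(coldat) <- sids

  MetaboliteExperiment(abundance = t(vals),
                       belowLOD = t(mask),
                       rowData = rowdat, colData = coldat, scale = scale)
}

#' Write a metabolite experiment as delimited text files
#'
#' Writes the matrix (samples x metabolites, masked cells as empty strings),
#' annotations and sample metadata as three CSV files that round-trip through
#' [readMetaboliteExperiment()].
#'
#' @param x a [MetaboliteExperiment-class].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix (default `"cohort"`).
#' @return invisibly, the named vector of written paths.
#' @export
writeMetaboliteExperiment <- function(x, dir, prefix = "cohort") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(matrix = file.path(dir, paste0(prefix, "_matrix.csv")),
             annotations = file.path(dir, paste0(prefix, "_annotations.csv")),
             metadata = file.path(dir, paste0(prefix, "_metadata.csv")))
  vals <- assayMatrix(x)
  chr <- matrix(vapply(vals, function(v)
    if (is.na(v)) "" else format(v, digits = 15), character(1)),
    nrow(vals), ncol(vals), dimnames = dimnames(vals))
  utils::write.csv(data.frame(sample_id = rownames(chr), chr,
                              check.names = FALSE),
                   paths["matrix"], row.names = FALSE, quote = FALSE)
  rd <- as.data.frame(SummarizedExperiment::rowData(x))
  utils::write.csv(data.frame(metabolite_id = rownames(x),
                              rd[, c("metabolite", "super_pathway",
                                     "sub_pathway", "is_drug")],
                              check.names = FALSE),
                   paths["annotations"], row.names = FALSE, quote = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  utils::write.csv(data.frame(sample_id = colnames(x), cd,
                              check.names = FALSE),
                   paths["metadata"], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
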