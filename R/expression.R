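#' Construct an expression matrix with sample metadata
#'
#' Bundles an RNA x sample RPKM matrix with the RNA type of every row
#' (\code{"gene"} or \code{"lincRNA"}) and per-sample metadata (tissue,
#' condition, time point with an hour-equivalent value, replicate).
#'
#' @param values numeric matrix of RPKM values (rows = RNAs, columns =
#'   samples); must be non-negative, with unique row names.
#' @param types named character vector mapping every RNA id to
#'   \code{"gene"} or \code{"lincRNA"}.
#' @param samples data frame with one row per sample and columns
#'   \code{sample}, \code{tissue}, \code{condition}, \code{timepoint},
#'   \code{hours} (numeric hour-equivalent of the time point, > 0) and
#'   \code{replicate}; \code{sample} must match the column names of
#'   \code{values}.
#' @return An object of class \code{expression_matrix}: a list with
#'   elements \code{values}, \code{types} and \code{samples}.
#' @export
expression_matrix <- function(values, types, samples) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression values need row (RNA) and column (sample) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate RNA ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  bad <- which(values < 0 | !is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("negative or non-finite RPKM at row '%s', column '%s'",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]))
  missing_type <- setdiff(rownames(values), names(types))
  if (length(missing_type) > 0)
    stop("RNAs without a declared type: ",
         paste(head(missing_type, 5), collapse = ", "))
  types <- types[rownames(values)]
  if (!all(types %in% c("gene", "lincRNA")))
    stop("RNA types must be 'gene' or 'lincRNA'")
  samples <- as.data.frame(samples)
  req <- c("sample", "tissue", "condition", "timepoint", "hours", "replicate")
  miss <- setdiff(req, names(samples))
  if (length(miss) > 0)
    stop("sample metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample))
    stop("duplicate sample ids in metadata")
  unknown <- setdiff(colnames(values), samples$sample)
  if (length(unknown) > 0)
    stop("expression column(s) without metadata: ",
         paste(unknown, collapse = ", "))
  if (any(!is.finite(samples$hours) | samples$hours <= 0))
    stop("hour-equivalent time values must be strictly positive")
  samples <- samples[match(colnames(values), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(values = values, types = types, samples = samples),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d RNAs (%d lincRNAs) x %d samples\n",
              nrow(x$values), sum(x$types == "lincRNA"), ncol(x$values)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Select samples of an expression matrix by metadata predicate
#'
#' @param expr an \code{\link{expression_matrix}}.
#' @param filter either \code{NULL} (all samples), a logical vector over
#'   samples, or a function taking the sample metadata data frame and
#'   returning a logical vector.
#' @return An \code{expression_matrix} restricted to the selected samples.
#' @export
filter_samples <- function(expr, filter = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  keep <- if (is.null(filter)) rep(TRUE, ncol(expr$values))
          else if (is.function(filter)) filter(expr$samples)
          else as.logical(filter)
  if (length(keep) != ncol(expr$values))
    stop("sample filter length does not match sample count")
  expression_matrix(expr$values[, keep, drop = FALSE], expr$types,
                    expr$samples[keep, , drop = FALSE])
}

#' Read an expression matrix and its sample metadata from TSV files
#'
#' The matrix file is tab-separated with RNA ids in the first column
#' (header \code{rna}) and one column per sample; a companion
#' \code{types} column is not stored in the matrix file but in the
#' metadata-independent types file written next to it by
#' \code{\link{write_expression}} (column \code{rna}, \code{type}).
#'
#' @param path matrix TSV path.
#' @param meta_path sample metadata TSV path (columns \code{sample},
#'   \code{tissue}, \code{condition}, \code{timepoint}, \code{hours},
#'   \code{replicate}).
#' @param types_path RNA type TSV path (columns \code{rna}, \code{type});
#'   defaults to \code{<path>.types.tsv}.
#' @return An \code{\link{expression_matrix}}.
#' @export
read_expression <- function(path, meta_path,
                            types_path = paste0(path, ".types.tsv")) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "rna")
    stop("expression matrix must have 'rna' as its first column")
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab$rna
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  ty <- read.delim(types_path, stringsAsFactors = FALSE)
  types <- setNames(ty$type, ty$rna)
  expression_matrix(values, types, meta)
}

#' Write an expression matrix to TSV files
#'
#' Writes the value matrix, the sample metadata and the RNA type table as
#' three tab-separated files; \code{\link{read_expression}} reverses this.
#'
#' @inheritParams read_expression
#' @param expr an \code{\link{expression_matrix}}.
#' @return Invisibly, \code{path}.
#' @export
write_expression <- function(expr, path, meta_path,
                             types_path = paste0(path, ".types.tsv")) {
  stopifnot(inherits(expr, "expression_matrix"))
  tab <- data.frame(rna = rownames(expr$values), expr$values,
                    check.names = FALSE)
  write_tsv(tab, path)
  write_tsv(expr$samples, meta_path)
  write_tsv(data.frame(rna = rownames(expr$values),
                       type = unname(expr$types)), types_path)
  invisible(path)
}
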