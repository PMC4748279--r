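#' Construct a miRNA -> target map
#'
#' @param targets named list mapping each miRNA id to a character vector of
#'   RNA ids it targets. Empty target sets are dropped; the miRNA universe
#'   is the set of retained miRNA ids.
#' @return An object of class \code{target_map}.
#' @export
target_map <- function(targets) {
  if (length(targets) == 0)
    return(structure(list(targets = setNames(list(), character())),
                     class = "target_map"))
  if (is.null(names(targets)) || any(names(targets) == ""))
    stop("every target set must be named by its miRNA id")
  targets <- lapply(targets, function(x) sort(unique(as.character(x))))
  targets <- targets[lengths(targets) > 0]
  targets <- targets[order(names(targets))]
  structure(list(targets = targets), class = "target_map")
}

#' @export
print.target_map <- function(x, ...) {
  cat(sprintf("target_map: %d miRNAs (universe), %d distinct targets\n",
              length(x$targets), length(unique(unlist(x$targets)))))
  invisible(x)
}

#' Size of the miRNA universe of a target map
#' @param tm a \code{\link{target_map}}.
#' @return Integer count of distinct miRNAs.
#' @export
mirna_universe_size <- function(tm) {
  stopifnot(inherits(tm, "target_map"))
  length(tm$targets)
}

#' Regulator sets per RNA
#'
#' Inverts a target map into a named list mapping each RNA id to the sorted
#' set of miRNAs that target it.
#'
#' @param tm a \code{\link{target_map}}.
#' @return Named list of character vectors.
#' @export
regulators_by_rna <- function(tm) {
  stopifnot(inherits(tm, "target_map"))
  if (length(tm$targets) == 0) return(list())
  long <- data.frame(
    mirna = rep(names(tm$targets), lengths(tm$targets)),
    rna = unlist(tm$targets, use.names = FALSE),
    stringsAsFactors = FALSE)
  split(long$mirna, long$rna)
}

#' Read a miRNA-target table
#'
#' Accepts either the minimal two-column form (miRNA id, target RNA id) or
#' full psRNATarget-style output, in which case only the miRNA and target
#' columns are used (columns named \code{miRNA_Acc.}/\code{miRNA} and
#' \code{Target_Acc.}/\code{Target}). Duplicate pairs are collapsed.
#'
#' @param path tab-separated file path.
#' @return A \code{\link{target_map}}; its universe is the set of distinct
#'   miRNA ids in the file.
#' @export
read_target_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(target_map(list()))
  first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  has_header <- any(c("mirna", "miRNA", "miRNA_Acc.") %in% first)
  if (has_header) {
    tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    mcol <- intersect(c("mirna", "miRNA", "miRNA_Acc."), names(tab))[1]
    tcol <- intersect(c("target", "Target", "Target_Acc."), names(tab))[1]
    if (is.na(mcol) || is.na(tcol))
      stop("target table header lacks miRNA/target columns")
    pairs <- data.frame(mirna = tab[[mcol]], target = tab[[tcol]],
                        stringsAsFactors = FALSE)
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 2)
    if (length(bad) > 0)
      stop(sprintf("malformed target-table row at line %d: '%s'",
                   bad[1], lines[bad[1]]))
    pairs <- data.frame(mirna = vapply(fields, `[`, "", 1),
                        target = vapply(fields, `[`, "", 2),
                        stringsAsFactors = FALSE)
  }
  if (any(!nzchar(pairs$mirna)) || any(!nzchar(pairs$target)))
    stop(sprintf("malformed target-table row at line %d",
                 which(!nzchar(pairs$mirna) | !nzchar(pairs$target))[1]))
  target_map(split(pairs$target, pairs$mirna))
}

#' Write a target map as a two-column TSV
#'
#' @param tm a \code{\link{target_map}}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_target_table <- function(tm, path) {
  stopifnot(inherits(tm, "target_map"))
  tab <- data.frame(
    mirna = rep(names(tm$targets), lengths(tm$targets)),
    target = unlist(tm$targets, use.names = FALSE))
  write_tsv(tab, path)
  invisible(path)
}
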