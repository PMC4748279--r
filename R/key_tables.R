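#' Published key-lincRNA tables (root and shoot)
#'
#' Loads the key-lincRNA reports of the phosphate-starvation rice study
#' shipped with the package: the differentially expressed hub lincRNAs of
#' the root (47 entries) and shoot (40 entries) ceRNA networks, with
#' their degrees and GO annotations where assigned.
#'
#' @param tissue \code{"root"} or \code{"shoot"}.
#' @return Data frame with columns \code{lincrna}, \code{degree},
#'   \code{go_id}, \code{go_name}.
#' @export
key_lincrna_table <- function(tissue = c("root", "shoot")) {
  tissue <- match.arg(tissue)
  path <- system.file("extdata",
                      sprintf("key_lincrnas_%s.tsv", tissue),
                      package = "lincnet", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
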