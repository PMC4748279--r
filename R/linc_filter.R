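#' Apply the lincRNA candidate filters
#'
#' A transcript is kept iff it satisfies all of, in this order:
#' \enumerate{
#'   \item \code{length >= min_length} (default 200 nt; transcripts
#'     smaller than 200 nt are removed, so exactly 200 is kept);
#'   \item its assembly class code marks it intergenic (Cufflinks-style
#'     \code{"u"});
#'   \item its RPKM reaches \code{min_rpkm} in at least one sample
#'     (transcripts below the floor in \emph{all} samples are removed);
#'   \item it is \emph{not} protein-similar: similarity hits with
#'     \code{coverage > sim_coverage} \emph{and}
#'     \code{e-value < sim_evalue} reject (a strict conjunction — either
#'     arm alone does not);
#'   \item neither coding-potential flag (CPAT-like, CPC-like) is set.
#' }
#' The rejection table records the first failed rule per transcript, in
#' the order above; the kept/rejected outcome itself is
#' order-independent.
#'
#' @param records candidate-transcript data frame: columns
#'   \code{transcript}, \code{length}, \code{class_code}, one or more
#'   \code{rpkm_*} columns, \code{sim_coverage}, \code{sim_evalue} (NA
#'   when no similarity hit), \code{cpat_coding}, \code{cpc_coding}.
#' @param min_length minimum transcript length in nt.
#' @param min_rpkm expression floor (must be reached in >= 1 sample).
#' @param sim_coverage,sim_evalue protein-similarity rejection thresholds.
#' @param intergenic_classes class codes counted as intergenic.
#' @return List with \code{kept} (the passing records) and
#'   \code{rejected} (columns \code{transcript}, \code{reason}).
#' @export
filter_candidates <- function(records, min_length = 200, min_rpkm = 0.5,
                              sim_coverage = 0.5, sim_evalue = 1e-5,
                              intergenic_classes = "u") {
  empty <- list(kept = records[0, , drop = FALSE],
                rejected = data.frame(transcript = character(),
                                      reason = character()))
  if (nrow(records) == 0) return(empty)
  rpkm_cols <- grep("^rpkm_", names(records))
  if (length(rpkm_cols) == 0) stop("records need at least one rpkm_* column")
  if (any(records$sim_coverage < 0 | records$sim_coverage > 1, na.rm = TRUE))
    stop("similarity coverage must lie in [0,1]")
  if (any(records$sim_evalue < 0, na.rm = TRUE))
    stop("similarity e-value must be >= 0")
  rpkm_max <- apply(as.matrix(records[, rpkm_cols, drop = FALSE]), 1, max)
  protein_similar <- !is.na(records$sim_coverage) &
    !is.na(records$sim_evalue) &
    records$sim_coverage > sim_coverage & records$sim_evalue < sim_evalue
  reason <- rep(NA_character_, nrow(records))
  fail <- function(cond, label) {
    reason[is.na(reason) & cond] <<- label
  }
  fail(records$length < min_length, "length")
  fail(!records$class_code %in% intergenic_classes, "class")
  fail(rpkm_max < min_rpkm, "expression")
  fail(protein_similar, "protein_similarity")
  fail(records$cpat_coding | records$cpc_coding, "coding_potential")
  kept <- records[is.na(reason), , drop = FALSE]
  rejected <- data.frame(transcript = records$transcript[!is.na(reason)],
                         reason = reason[!is.na(reason)])
  rownames(kept) <- NULL
  list(kept = kept, rejected = rejected)
}
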