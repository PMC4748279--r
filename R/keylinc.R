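# Hub selection and key-lincRNA prioritization: hubs are the top 20% of
# nodes by degree; key lincRNAs are hub lincRNAs differentially expressed
# at any time point of the stress time course.

#' Degree threshold and hub set of a network
#'
#' Sorts node degrees in decreasing order, takes the first
#' \code{floor(fraction * n)} nodes (at least one) and includes every node
#' tied with the last included degree. The realized threshold is the
#' largest degree among non-hubs, so every hub has degree strictly above
#' it.
#'
#' @param net igraph network with at least one node, or a named numeric
#'   vector of node degrees.
#' @param fraction hub fraction (default 0.2, the top 20\%).
#' @return List with \code{threshold} (numeric) and \code{hubs}
#'   (character vector of node ids).
#' @export
hub_threshold <- function(net, fraction = 0.2) {
  deg <- if (igraph::is_igraph(net)) igraph::degree(net) else net
  n <- length(deg)
  if (n == 0) stop("empty network has no hubs")
  if (is.null(names(deg))) stop("degrees must be named by node id")
  k <- max(1L, floor(fraction * n))
  cutoff <- sort(deg, decreasing = TRUE)[k]
  hubs <- names(deg)[deg >= cutoff]
  non_hub <- deg[deg < cutoff]
  if (length(non_hub) == 0) {
    if (n > 1)
      warning("all nodes tied at the hub boundary: every node is a hub")
    threshold <- min(deg) - 1
  } else {
    threshold <- max(non_hub)
  }
  list(threshold = threshold, hubs = sort(hubs))
}

#' Select key lincRNAs: differentially expressed hub lincRNAs
#'
#' @param net ceRNA network.
#' @param hubs result of \code{\link{hub_threshold}} (or a character
#'   vector of hub node ids).
#' @param de DE table (columns \code{rna}, \code{timepoint}, \code{fdr}).
#' @param annotations optional lincRNA annotation table from
#'   \code{\link{annotate_lincrnas}}.
#' @param fdr_threshold significance level on the FDR (default 0.05); a
#'   lincRNA counts as differentially expressed when its FDR is below the
#'   threshold at one or more time points.
#' @param tissue label stored in the report.
#' @return A key-lincRNA report: list with \code{tissue},
#'   \code{threshold} (degree threshold when \code{hubs} came from
#'   \code{\link{hub_threshold}}) and \code{lincrnas}, a data frame
#'   (\code{lincrna}, \code{degree}, \code{go_id}, \code{go_name}) sorted
#'   by decreasing degree.
#' @export
select_key_lincrnas <- function(net, hubs, de, annotations = NULL,
                                fdr_threshold = 0.05, tissue = "root") {
  threshold <- NA_real_
  if (is.list(hubs)) {
    threshold <- hubs$threshold
    hubs <- hubs$hubs
  }
  types <- setNames(igraph::V(net)$type, igraph::V(net)$name)
  deg <- igraph::degree(net)
  hub_lincs <- hubs[types[hubs] == "lincRNA"]
  de_ok <- unique(de$rna[de$fdr < fdr_threshold])
  key <- intersect(hub_lincs, de_ok)
  tab <- data.frame(lincrna = key, degree = as.integer(deg[key]),
                    go_id = NA_character_, go_name = NA_character_)
  if (!is.null(annotations) && nrow(tab) > 0) {
    i <- match(tab$lincrna, annotations$lincrna)
    tab$go_id <- annotations$go_id[i]
    tab$go_name <- annotations$go_name[i]
  }
  tab <- tab[order(-tab$degree, tab$lincrna), , drop = FALSE]
  rownames(tab) <- NULL
  list(tissue = tissue, threshold = threshold, lincrnas = tab)
}

#' Compare two key-lincRNA reports
#'
#' @param a,b key-lincRNA reports from \code{\link{select_key_lincrnas}}
#'   (or bare character vectors of lincRNA ids).
#' @return List with \code{common}, \code{only_a}, \code{only_b} (sorted
#'   id vectors).
#' @export
compare_key_sets <- function(a, b) {
  ids <- function(x) if (is.list(x)) x$lincrnas$lincrna else as.character(x)
  a <- unique(ids(a)); b <- unique(ids(b))
  list(common = sort(intersect(a, b)),
       only_a = sort(setdiff(a, b)),
       only_b = sort(setdiff(b, a)))
}

#' Hierarchical clustering of samples on selected feature RNAs
#'
#' Samples are clustered on log2(RPKM + 1) profiles of the feature RNAs
#' with correlation distance and average linkage — the Eisen-style
#' recipe for expression heatmaps. As in that recipe, each feature row
#' is mean-centered first (so sample similarity reflects shared response
#' patterns rather than the features' arbitrary baseline abundances) and
#' the similarity is the uncentered correlation (Eisen's correlation
#' with the offset fixed at zero): unlike the centered form, it is not
#' blind to a response shared by all features, which is precisely the
#' signature that distinguishes stress stages. The flat 2-group
#' partition is the top-level cut of the tree.
#'
#' @param expr an \code{\link{expression_matrix}}.
#' @param features RNA ids (typically key lincRNAs) used as clustering
#'   features.
#' @param sample_filter sample selection (see \code{\link{filter_samples}});
#'   at least 2 samples must remain.
#' @return List with \code{tree} (an \code{hclust} over samples) and
#'   \code{groups} (named integer vector, the 2-group cut).
#' @export
cluster_samples <- function(expr, features, sample_filter = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  sub <- filter_samples(expr, sample_filter)
  if (ncol(sub$values) < 2) stop("need at least 2 samples to cluster")
  features <- intersect(features, rownames(sub$values))
  if (length(features) == 0) stop("no clustering features present")
  mat <- log2(sub$values[features, , drop = FALSE] + 1)
  vr <- apply(mat, 1, function(v) var(v) > 0)
  if (!any(vr)) stop("clustering undefined: all features have zero variance")
  mat <- mat - rowMeans(mat)
  norms <- sqrt(colSums(mat^2))
  cc <- crossprod(mat) / outer(norms, norms)
  if (any(!is.finite(cc)))
    stop("clustering undefined: a sample profile has zero norm")
  tree <- hclust(as.dist(1 - cc), method = "average")
  groups <- cutree(tree, k = 2)
  list(tree = tree, groups = groups)
}

#' Two-group differential expression per time point (Welch test)
#'
#' A deliberately simple stand-in used to close the loop on synthetic
#' data: per RNA and time point, a two-sided Welch t-test on
#' log2(RPKM + 1) replicate values between the two conditions,
#' Benjamini-Hochberg corrected across RNAs within the time point. It is
#' not equivalent to count-based DE models (edgeR-style) and is not
#' intended for real read-count data.
#'
#' @param expr an \code{\link{expression_matrix}}.
#' @param conditions length-2 character vector naming the two conditions
#'   to contrast.
#' @param timepoints time points to test (default: all in the metadata).
#' @return DE table (\code{rna}, \code{timepoint}, \code{fdr}) plus a
#'   \code{p} column of raw p-values.
#' @export
simple_de <- function(expr, conditions = c("control", "starved"),
                      timepoints = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  meta <- expr$samples
  if (is.null(timepoints)) timepoints <- unique(meta$timepoint)
  lv <- log2(expr$values + 1)
  out <- list()
  for (tp in timepoints) {
    i1 <- which(meta$timepoint == tp & meta$condition == conditions[1])
    i2 <- which(meta$timepoint == tp & meta$condition == conditions[2])
    if (length(i1) < 2 || length(i2) < 2)
      stop(sprintf("need >= 2 replicates per condition at time point '%s'",
                   tp))
    p <- welch_p(lv[, i1, drop = FALSE], lv[, i2, drop = FALSE])
    out[[length(out) + 1]] <- data.frame(
      rna = rownames(lv), timepoint = tp, p = p,
      fdr = p.adjust(p, method = "BH"))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("rna", "timepoint", "fdr", "p")]
}

# vectorized two-sided Welch t-test across matrix rows
welch_p <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1, var); v2 <- apply(x2, 1, var)
  se2 <- v1 / n1 + v2 / n2
  p <- numeric(length(m1))
  zero <- se2 == 0
  p[zero] <- ifelse(m1[zero] == m2[zero], 1, 0)
  t_stat <- (m1[!zero] - m2[!zero]) / sqrt(se2[!zero])
  df <- se2[!zero]^2 /
    ((v1[!zero] / n1)^2 / (n1 - 1) + (v2[!zero] / n2)^2 / (n2 - 1))
  p[!zero] <- 2 * pt(-abs(t_stat), df = df)
  p
}
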