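#' Hypergeometric upper-tail overlap probability
#'
#' Probability that a uniformly random \code{N}-subset of a universe of
#' size \code{U} overlaps a fixed \code{M}-subset in at least \code{n}
#' elements: \eqn{P(X \ge n) = \sum_{i=n}^{\min(M,N)} C(M,i) C(U-M,N-i) /
#' C(U,N)}. This is the significance test applied both to shared miRNA
#' regulator sets of an RNA pair and to GO term over-representation.
#'
#' Computed through the hypergeometric survival function, which is
#' numerically stable for universes well beyond 1e5.
#'
#' @param n observed overlap (vectorized).
#' @param M size of the fixed subset (regulators of RNA A; or query genes).
#' @param N size of the random subset (regulators of RNA B; or term genes).
#' @param U universe size.
#' @return Upper-tail probability in [0, 1], vectorized over the inputs.
#' @export
hypergeom_upper_tail <- function(n, M, N, U) {
  if (any(U < 1)) stop("universe size U must be >= 1")
  if (any(M > U) || any(N > U)) stop("M and N must not exceed U")
  if (any(n < 0) || any(n > pmin(M, N)))
    stop("overlap n must satisfy 0 <= n <= min(M, N)")
  phyper(n - 1, M, U - M, N, lower.tail = FALSE)
}

#' Nominate candidate ceRNA pairs by shared-regulator significance
#'
#' Evaluates every unordered pair of eligible RNAs: the overlap of their
#' miRNA regulator sets is tested with \code{\link{hypergeom_upper_tail}}
#' against the miRNA universe of the target map, and pairs with
#' \code{p < alpha_overlap} are returned. RNAs with no regulator in the
#' target map are excluded up front (their count is reported via
#' \code{message}).
#'
#' @param targets a \code{\link{target_map}}.
#' @param rnas character vector of eligible RNA ids; defaults to every RNA
#'   appearing in the target map.
#' @param alpha_overlap significance threshold on the overlap p-value.
#' @return Data frame sorted lexicographically by pair, with columns
#'   \code{rna_a}, \code{rna_b}, \code{shared_count}, \code{m}, \code{n},
#'   \code{p_overlap}.
#' @export
candidate_pairs <- function(targets, rnas = NULL, alpha_overlap = 0.05) {
  stopifnot(inherits(targets, "target_map"))
  U <- mirna_universe_size(targets)
  if (U < 1) stop("empty miRNA universe")
  regs <- regulators_by_rna(targets)
  if (is.null(rnas)) rnas <- names(regs)
  rnas <- sort(unique(as.character(rnas)))
  dropped <- setdiff(rnas, names(regs))
  if (length(dropped) > 0)
    message(length(dropped), " RNA(s) without miRNA regulators excluded")
  rnas <- intersect(rnas, names(regs))
  if (length(rnas) < 2)
    return(data.frame(rna_a = character(), rna_b = character(),
                      shared_count = integer(), m = integer(), n = integer(),
                      p_overlap = numeric()))
  # incidence matrix miRNA x RNA; shared counts by crossprod
  mirnas <- names(targets$targets)
  inc <- matrix(FALSE, length(mirnas), length(rnas),
                dimnames = list(mirnas, rnas))
  for (r in rnas) inc[regs[[r]], r] <- TRUE
  shared <- crossprod(inc)
  sizes <- diag(shared)
  idx <- which(upper.tri(shared), arr.ind = TRUE)
  p <- hypergeom_upper_tail(shared[idx], sizes[idx[, 1]], sizes[idx[, 2]], U)
  keep <- p < alpha_overlap
  out <- data.frame(rna_a = rnas[idx[keep, 1]], rna_b = rnas[idx[keep, 2]],
                    shared_count = as.integer(shared[idx][keep]),
                    m = as.integer(sizes[idx[keep, 1]]),
                    n = as.integer(sizes[idx[keep, 2]]),
                    p_overlap = p[keep])
  out <- out[order(out$rna_a, out$rna_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation with a two-sided t-approximation p-value
#'
#' Ranks with ties sharing mean ranks; the p-value comes from the
#' t-statistic \eqn{\rho \sqrt{(m-2)/(1-\rho^2)}} on \eqn{m-2} degrees of
#' freedom (two-sided). \eqn{\rho = \pm 1} gives p = 0.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return List with \code{rho} and \code{p}; both \code{NA} (with
#'   \code{defined = FALSE}) when either series has zero variance.
#' @export
spearman_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("series must have equal length")
  m <- length(x)
  if (m < 3) stop("need at least 3 paired observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    return(list(rho = NA_real_, p = NA_real_, defined = FALSE))
  rho <- cor(rank(x), rank(y))
  p <- spearman_p(rho, m)
  list(rho = rho, p = p, defined = TRUE)
}

spearman_p <- function(rho, m) {
  p <- numeric(length(rho))
  ex <- abs(rho) >= 1 - 1e-12
  p[ex] <- 0
  t_stat <- rho[!ex] * sqrt((m - 2) / (1 - rho[!ex]^2))
  p[!ex] <- 2 * pt(-abs(t_stat), df = m - 2)
  p
}

#' Assemble the ceRNA network from candidate pairs
#'
#' Each candidate pair is confirmed by Spearman correlation of the two
#' RNAs' RPKM profiles over the selected samples: pairs with \code{rho > 0}
#' and \code{p_rho < alpha_corr} become edges. Pairs in which either RNA
#' has zero expression variance over the selected samples are dropped (a
#' count is reported via \code{message}). The result keeps only nodes
#' incident to at least one retained edge; node types are copied from the
#' expression matrix.
#'
#' @param candidates data frame from \code{\link{candidate_pairs}}.
#' @param expr an \code{\link{expression_matrix}} containing every
#'   candidate RNA.
#' @param sample_filter sample selection (see \code{\link{filter_samples}});
#'   must retain at least 3 samples. The study design evaluates ceRNA
#'   co-expression over the stress-condition samples of one tissue.
#' @param alpha_corr significance threshold on the correlation p-value.
#' @return An undirected simple igraph network with vertex attribute
#'   \code{type} and edge attributes \code{shared_count}, \code{p_overlap},
#'   \code{rho}, \code{p_rho}.
#' @export
build_network <- function(candidates, expr, sample_filter = NULL,
                          alpha_corr = 0.05) {
  stopifnot(inherits(expr, "expression_matrix"))
  sub <- filter_samples(expr, sample_filter)
  m <- ncol(sub$values)
  if (m < 3) stop("sample filter must select at least 3 samples")
  if (nrow(candidates) == 0)
    return(empty_cerna_network())
  missing <- setdiff(unique(c(candidates$rna_a, candidates$rna_b)),
                     rownames(sub$values))
  if (length(missing) > 0)
    stop("candidate RNA(s) absent from expression matrix: ",
         paste(head(missing, 5), collapse = ", "))
  vals <- sub$values[unique(c(candidates$rna_a, candidates$rna_b)), ,
                     drop = FALSE]
  rk <- t(apply(vals, 1, rank))
  constant <- apply(vals, 1, function(v) length(unique(v)) < 2)
  rk <- sweep(rk, 1, rowMeans(rk))
  norm <- sqrt(rowSums(rk^2))
  a <- candidates$rna_a
  b <- candidates$rna_b
  undef <- constant[a] | constant[b]
  if (any(undef))
    message(sum(undef), " candidate pair(s) with zero-variance expression dropped")
  rho <- rowSums(rk[a, , drop = FALSE] * rk[b, , drop = FALSE]) /
    (norm[a] * norm[b])
  rho[undef] <- NA_real_
  p_rho <- rep(NA_real_, length(rho))
  p_rho[!undef] <- spearman_p(rho[!undef], m)
  keep <- !undef & rho > 0 & p_rho < alpha_corr
  if (!any(keep)) return(empty_cerna_network())
  edges <- data.frame(from = a[keep], to = b[keep],
                      shared_count = candidates$shared_count[keep],
                      p_overlap = candidates$p_overlap[keep],
                      rho = rho[keep], p_rho = p_rho[keep])
  nodes <- sort(unique(c(edges$from, edges$to)))
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = nodes, type = unname(expr$types[nodes])))
  g
}

empty_cerna_network <- function() {
  igraph::make_empty_graph(0, directed = FALSE)
}

#' Check ceRNA edge criteria on every stored edge
#'
#' Asserts that each edge carries a significant overlap p-value, a positive
#' Spearman rho and a significant correlation p-value.
#'
#' @param net ceRNA network from \code{\link{build_network}}.
#' @param alpha_overlap,alpha_corr the thresholds the network was built
#'   with.
#' @return \code{TRUE} invisibly; stops on the first violated criterion.
#' @export
validate_network <- function(net, alpha_overlap = 0.05, alpha_corr = 0.05) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::ecount(net) == 0) return(invisible(TRUE))
  if (any(igraph::which_loop(net))) stop("network contains self-loops")
  if (any(igraph::which_multiple(net))) stop("network contains parallel edges")
  if (any(igraph::E(net)$p_overlap >= alpha_overlap))
    stop("edge with non-significant regulator overlap")
  if (any(igraph::E(net)$rho <= 0)) stop("edge with non-positive rho")
  if (any(igraph::E(net)$p_rho >= alpha_corr))
    stop("edge with non-significant correlation")
  invisible(TRUE)
}

#' Average degree of a network
#'
#' @param net igraph network with at least one node.
#' @return \code{2 * |edges| / |nodes|}.
#' @export
average_degree <- function(net) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::vcount(net) == 0) stop("empty network has no average degree")
  2 * igraph::ecount(net) / igraph::vcount(net)
}

#' Log-log power-law fit of a degree distribution
#'
#' Builds the degree-frequency table (zero-frequency degrees omitted,
#' degree-0 nodes excluded) and fits ordinary least squares of
#' log10(frequency) on log10(degree). Scale-free networks show a strong
#' negative linear trend on this plot.
#'
#' @param net igraph network with at least 3 distinct positive degrees.
#' @return List with \code{exponent} (negated slope), \code{correlation}
#'   (Pearson correlation of the log-log points, typically negative) and
#'   \code{r_squared}, plus the degree-frequency \code{table}.
#' @export
degree_powerlaw_fit <- function(net) {
  stopifnot(igraph::is_igraph(net))
  deg <- igraph::degree(net)
  deg <- deg[deg > 0]
  freq <- table(deg)
  powerlaw_fit_points(as.numeric(names(freq)), as.numeric(freq))
}

# OLS fit of log10(frequency) on log10(degree) over a degree-frequency
# table; shared by degree_powerlaw_fit and its tests
powerlaw_fit_points <- function(k, f) {
  if (length(k) < 3)
    stop("power-law fit undefined: fewer than 3 distinct degrees")
  lx <- log10(k)
  ly <- log10(f)
  fit <- lm(ly ~ lx)
  r <- cor(lx, ly)
  list(exponent = -unname(coef(fit)[2]), correlation = r, r_squared = r^2,
       table = data.frame(degree = k, frequency = f))
}

#' Topology report of a ceRNA network
#'
#' @param net ceRNA network.
#' @return List with node/edge counts, lincRNA count, average degree and,
#'   when defined, the power-law fit.
#' @export
topology_report <- function(net) {
  fit <- tryCatch(degree_powerlaw_fit(net), error = function(e) NULL)
  list(nodes = igraph::vcount(net), edges = igraph::ecount(net),
       lincrnas = sum(igraph::V(net)$type == "lincRNA"),
       average_degree = average_degree(net), powerlaw = fit)
}
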