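# GO over-representation and the three-tier lincRNA annotation rule.
# Only genes carry GO annotations: lincRNAs are annotated by association —
# through their community, or failing that through their direct gene
# neighbors in the ceRNA network.

#' GO term over-representation of a gene set
#'
#' Tests every GO term with at least one query gene with the
#' hypergeometric upper tail (\code{\link{hypergeom_upper_tail}}):
#' n = |query genes in the term|, M = |query genes in the universe|,
#' N = |term genes in the universe|, U = |universe|. The query is
#' intersected with the universe before testing, so lincRNAs (which carry
#' no GO annotations) never inflate M.
#'
#' @param query character vector of gene ids.
#' @param go GO annotation table (columns \code{gene}, \code{go_id},
#'   \code{go_name}).
#' @param universe gene universe; defaults to every gene with at least one
#'   annotation in \code{go}.
#' @param alpha significance threshold.
#' @return Data frame of enriched terms (\code{go_id}, \code{go_name},
#'   \code{n}, \code{m}, \code{term_size}, \code{universe_size}, \code{p})
#'   with \code{p < alpha}, sorted by ascending p, ties by GO id.
#' @export
go_enrichment <- function(query, go, universe = NULL, alpha = 0.05) {
  if (is.null(universe)) universe <- unique(go$gene)
  universe <- unique(universe)
  U <- length(universe)
  if (U < 1) stop("empty enrichment universe")
  go <- go[go$gene %in% universe, , drop = FALSE]
  query <- intersect(unique(query), universe)
  M <- length(query)
  empty <- data.frame(go_id = character(), go_name = character(),
                      n = integer(), m = integer(), term_size = integer(),
                      universe_size = integer(), p = numeric())
  if (M == 0) return(empty)
  hits <- go[go$gene %in% query, , drop = FALSE]
  if (nrow(hits) == 0) return(empty)
  n_by_term <- tapply(hits$gene, hits$go_id, function(g) length(unique(g)))
  terms <- names(n_by_term)
  N_by_term <- tapply(go$gene, go$go_id, function(g) length(unique(g)))
  nm_by_term <- tapply(go$go_name, go$go_id, `[`, 1)
  res <- data.frame(
    go_id = terms,
    go_name = unname(nm_by_term[terms]),
    n = as.integer(n_by_term),
    m = M,
    term_size = as.integer(N_by_term[terms]),
    universe_size = U,
    p = hypergeom_upper_tail(as.integer(n_by_term), M,
                             as.integer(N_by_term[terms]), U))
  res <- res[res$p < alpha, , drop = FALSE]
  res <- res[order(res$p, res$go_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Annotate communities with their most significant GO term
#'
#' Runs \code{\link{go_enrichment}} on the gene members of each community
#' (node types taken from the network); the minimum-p enriched term becomes
#' the community annotation. Ties at identical p go to the
#' lexicographically smaller GO id. Communities with no enriched term (or
#' no gene members) are reported as unannotated.
#'
#' @param communities list from \code{\link{find_complexes}}.
#' @param net the ceRNA network the communities were mined from.
#' @param go GO annotation table.
#' @param universe enrichment universe (see \code{\link{go_enrichment}}).
#' @param alpha significance threshold.
#' @return Data frame with one row per community: \code{community},
#'   \code{go_id}, \code{go_name}, \code{p} (NA when unannotated) and
#'   \code{annotated}; the fraction annotated is attached as attribute
#'   \code{fraction_annotated}.
#' @export
annotate_communities <- function(communities, net, go, universe = NULL,
                                 alpha = 0.05) {
  types <- setNames(igraph::V(net)$type, igraph::V(net)$name)
  rows <- lapply(communities, function(cm) {
    genes <- cm$members[types[cm$members] == "gene"]
    top <- if (length(genes) > 0)
      head(go_enrichment(genes, go, universe, alpha), 1) else NULL
    if (is.null(top) || nrow(top) == 0)
      data.frame(community = cm$id, go_id = NA_character_,
                 go_name = NA_character_, p = NA_real_, annotated = FALSE)
    else
      data.frame(community = cm$id, go_id = top$go_id,
                 go_name = top$go_name, p = top$p, annotated = TRUE)
  })
  out <- if (length(rows) > 0) do.call(rbind, rows)
         else data.frame(community = integer(), go_id = character(),
                         go_name = character(), p = numeric(),
                         annotated = logical())
  attr(out, "fraction_annotated") <-
    if (nrow(out) > 0) mean(out$annotated) else NA_real_
  out
}

#' Three-tier functional annotation of lincRNAs
#'
#' Every lincRNA node of the network receives at most one GO term:
#' \describe{
#'   \item{tier \code{community}}{the lincRNA belongs to an annotated
#'     community and inherits its term (if it belongs to several — only
#'     possible with fluff — the highest-scoring community wins).}
#'   \item{tier \code{neighbor_enrichment}}{otherwise its direct gene
#'     neighbors are tested with \code{\link{go_enrichment}}; the top
#'     enriched term is assigned.}
#'   \item{tier \code{neighbor_majority}}{otherwise the term annotating
#'     the largest number of distinct gene neighbors is assigned (ties by
#'     GO id); no p-value applies.}
#' }
#' LincRNAs with no annotated neighbors remain unannotated and are omitted
#' from the result.
#'
#' @param net ceRNA network.
#' @param communities list from \code{\link{find_complexes}}.
#' @param community_annotations data frame from
#'   \code{\link{annotate_communities}}.
#' @param go GO annotation table.
#' @param universe enrichment universe.
#' @param alpha significance threshold.
#' @return Data frame with columns \code{lincrna}, \code{go_id},
#'   \code{go_name}, \code{tier}, \code{p} (NA for
#'   \code{neighbor_majority}) and \code{community} (NA unless tier is
#'   \code{community}).
#' @export
annotate_lincrnas <- function(net, communities, community_annotations, go,
                              universe = NULL, alpha = 0.05) {
  types <- setNames(igraph::V(net)$type, igraph::V(net)$name)
  lincs <- names(types)[types == "lincRNA"]
  ann_comm <- community_annotations[community_annotations$annotated, ,
                                    drop = FALSE]
  # membership: lincRNA -> annotated communities holding it
  memb <- list()
  for (cm in communities) {
    if (!cm$id %in% ann_comm$community) next
    for (v in intersect(cm$members, lincs))
      memb[[v]] <- rbind(memb[[v]],
                         data.frame(community = cm$id, score = cm$score))
  }
  rows <- list()
  for (lc in lincs) {
    row <- NULL
    if (!is.null(memb[[lc]])) {
      best <- memb[[lc]][order(-memb[[lc]]$score, memb[[lc]]$community), ][1, ]
      ca <- ann_comm[ann_comm$community == best$community, ][1, ]
      row <- data.frame(lincrna = lc, go_id = ca$go_id, go_name = ca$go_name,
                        tier = "community", p = ca$p,
                        community = ca$community)
    } else {
      nbrs <- igraph::neighbors(net, lc)$name
      gene_nbrs <- nbrs[types[nbrs] == "gene"]
      if (length(gene_nbrs) > 0) {
        top <- head(go_enrichment(gene_nbrs, go, universe, alpha), 1)
        if (nrow(top) == 1) {
          row <- data.frame(lincrna = lc, go_id = top$go_id,
                            go_name = top$go_name,
                            tier = "neighbor_enrichment", p = top$p,
                            community = NA_integer_)
        } else {
          hits <- go[go$gene %in% gene_nbrs, , drop = FALSE]
          if (nrow(hits) > 0) {
            counts <- tapply(hits$gene, hits$go_id,
                             function(g) length(unique(g)))
            best_id <- sort(names(counts)[counts == max(counts)])[1]
            row <- data.frame(
              lincrna = lc, go_id = best_id,
              go_name = hits$go_name[match(best_id, hits$go_id)],
              tier = "neighbor_majority", p = NA_real_,
              community = NA_integer_)
          }
        }
      }
    }
    if (!is.null(row)) rows[[length(rows) + 1]] <- row
  }
  out <- if (length(rows) > 0) do.call(rbind, rows)
         else data.frame(lincrna = character(), go_id = character(),
                         go_name = character(), tier = character(),
                         p = numeric(), community = integer())
  rownames(out) <- NULL
  validate_linc_annotations(out, alpha)
  out
}

# tier/field consistency, run on every annotation result
validate_linc_annotations <- function(ann, alpha) {
  if (nrow(ann) == 0) return(invisible(TRUE))
  if (anyDuplicated(ann$lincrna))
    stop("a lincRNA received more than one annotation")
  comm <- ann$tier == "community"
  if (any(comm & (is.na(ann$community) | is.na(ann$p) | ann$p >= alpha)))
    stop("community-tier annotation without community id or significant p")
  if (any(ann$tier == "neighbor_majority" & !is.na(ann$p)))
    stop("neighbor_majority annotation must not carry a p-value")
  invisible(TRUE)
}
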