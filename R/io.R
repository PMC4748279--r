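# Flat-table readers/writers shared by the pipeline. All tables are
# tab-separated with a header row; parsers report the first offending line.

write_tsv <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a gene -> GO annotation table
#'
#' Rows are (gene id, GO id, GO name); the GO name is cosmetic and may be
#' empty — term identity is the GO id.
#'
#' @param path tab-separated file with columns \code{gene}, \code{go_id},
#'   \code{go_name} (header required; \code{go_name} may be missing).
#' @return Data frame with columns \code{gene}, \code{go_id},
#'   \code{go_name}, duplicates collapsed.
#' @export
read_go_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "go_id") %in% names(tab)))
    stop("GO table must have columns 'gene' and 'go_id'")
  if (is.null(tab$go_name)) tab$go_name <- ""
  tab$go_name[is.na(tab$go_name)] <- ""
  bad <- which(!nzchar(tab$gene) | !nzchar(tab$go_id))
  if (length(bad) > 0)
    stop(sprintf("malformed GO-table row at line %d (empty gene or GO id)",
                 bad[1] + 1L))
  tab <- tab[!duplicated(tab[, c("gene", "go_id")]),
             c("gene", "go_id", "go_name")]
  rownames(tab) <- NULL
  tab
}

#' Write a gene -> GO annotation table
#' @param go data frame with columns \code{gene}, \code{go_id},
#'   \code{go_name}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_go_table <- function(go, path) {
  write_tsv(go[, c("gene", "go_id", "go_name")], path)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Rows are (RNA id, time point, FDR); FDR values must lie in [0, 1] and
#' (RNA, time point) pairs must be unique.
#'
#' @param path tab-separated file with columns \code{rna},
#'   \code{timepoint}, \code{fdr}.
#' @return Data frame with those columns.
#' @export
read_de_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("rna", "timepoint", "fdr") %in% names(tab)))
    stop("DE table must have columns 'rna', 'timepoint', 'fdr'")
  bad <- which(!is.finite(tab$fdr) | tab$fdr < 0 | tab$fdr > 1)
  if (length(bad) > 0)
    stop(sprintf("DE-table FDR out of [0,1] at line %d (value %s)",
                 bad[1] + 1L, tab$fdr[bad[1]]))
  if (anyDuplicated(tab[, c("rna", "timepoint")]))
    stop("duplicate (rna, timepoint) pair in DE table")
  tab[, c("rna", "timepoint", "fdr")]
}

#' Write a differential-expression table
#' @param de data frame with columns \code{rna}, \code{timepoint},
#'   \code{fdr}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_de_table <- function(de, path) {
  write_tsv(de[, c("rna", "timepoint", "fdr")], path)
  invisible(path)
}

#' Export a ceRNA network
#'
#' Writes an edge-list TSV (columns \code{node_a}, \code{node_b},
#' \code{shared_count}, \code{p_overlap}, \code{rho}, \code{p_rho}), a node
#' table (\code{node}, \code{type}) and, optionally, GraphML with the node
#' \code{type} attribute.
#'
#' @param net an igraph ceRNA network (see \code{\link{build_network}}).
#' @param path edge-list TSV path; the node table goes to
#'   \code{<path>.nodes.tsv}.
#' @param graphml_path optional GraphML output path.
#' @return Invisibly, \code{path}.
#' @export
write_network <- function(net, path, graphml_path = NULL) {
  stopifnot(igraph::is_igraph(net))
  el <- igraph::as_edgelist(net)
  tab <- data.frame(node_a = el[, 1], node_b = el[, 2],
                    shared_count = edge_attr_or(net, "shared_count", NA),
                    p_overlap = edge_attr_or(net, "p_overlap", NA),
                    rho = edge_attr_or(net, "rho", NA),
                    p_rho = edge_attr_or(net, "p_rho", NA))
  write_tsv(tab, path)
  write_tsv(data.frame(node = igraph::V(net)$name,
                       type = igraph::V(net)$type), paste0(path, ".nodes.tsv"))
  if (!is.null(graphml_path))
    igraph::write_graph(net, graphml_path, format = "graphml")
  invisible(path)
}

edge_attr_or <- function(net, attr, default) {
  v <- igraph::edge_attr(net, attr)
  if (is.null(v)) rep(default, igraph::ecount(net)) else v
}

#' Import a ceRNA network written by \code{\link{write_network}}
#'
#' @param path edge-list TSV path (node table expected at
#'   \code{<path>.nodes.tsv}).
#' @return An igraph network with node \code{type} and edge attributes
#'   \code{shared_count}, \code{p_overlap}, \code{rho}, \code{p_rho}.
#' @export
read_network <- function(path) {
  edges <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("node_a", "node_b", "shared_count", "p_overlap", "rho", "p_rho")
  miss <- setdiff(need, names(edges))
  if (length(miss) > 0)
    stop("network edge list missing column(s): ", paste(miss, collapse = ", "))
  nodes <- read.delim(paste0(path, ".nodes.tsv"), stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  g
}

#' Write MCODE communities as a membership table
#'
#' @param communities list of communities from \code{\link{find_complexes}}.
#' @param path output TSV path (columns \code{community}, \code{member},
#'   \code{seed}, \code{score}).
#' @return Invisibly, \code{path}.
#' @export
write_communities <- function(communities, path) {
  if (length(communities) == 0) {
    write_tsv(data.frame(community = integer(), member = character(),
                         seed = character(), score = numeric()), path)
    return(invisible(path))
  }
  tab <- do.call(rbind, lapply(communities, function(cm)
    data.frame(community = cm$id, member = cm$members, seed = cm$seed,
               score = cm$score)))
  write_tsv(tab, path)
  invisible(path)
}

#' Read a community membership table written by
#' \code{\link{write_communities}}
#'
#' @param path TSV path.
#' @return List of communities, each a list with \code{id}, \code{members},
#'   \code{seed} and \code{score}.
#' @export
read_communities <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("community", "member", "seed", "score")
  if (!all(need %in% names(tab)))
    stop("community table must have columns ", paste(need, collapse = ", "))
  lapply(split(tab, tab$community), function(d)
    list(id = d$community[1], members = sort(d$member), seed = d$seed[1],
         score = d$score[1]))
}

#' Write lincRNA annotations
#'
#' @param ann data frame from \code{\link{annotate_lincrnas}} (columns
#'   \code{lincrna}, \code{go_id}, \code{go_name}, \code{tier}, \code{p},
#'   \code{community}).
#' @param path output TSV path.
#' @return Invisibly, \code{path}.
#' @export
write_annotations <- function(ann, path) {
  write_tsv(ann[, c("lincrna", "go_id", "go_name", "tier", "p", "community")],
            path)
  invisible(path)
}

#' Read lincRNA annotations written by \code{\link{write_annotations}}
#' @param path TSV path.
#' @return Data frame with columns \code{lincrna}, \code{go_id},
#'   \code{go_name}, \code{tier}, \code{p}, \code{community}.
#' @export
read_annotations <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("lincrna", "go_id", "go_name", "tier", "p", "community")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("annotation table missing column(s): ", paste(miss, collapse = ", "))
  tab[, need]
}
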