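# Molecular Complex Detection (MCODE): weight vertices by the core
# structure of their closed neighborhood, then greedily grow dense
# complexes outward from high-weight seeds. Implemented from scratch on
# igraph primitives; every tie-break is lexicographic by node id so runs
# are reproducible regardless of node insertion order.

#' MCODE parameters
#'
#' Defaults follow the Cytoscape MCODE plugin defaults: degree cutoff 2,
#' node score cutoff 0.2, k-core 2, max depth 100, haircut on, fluff off.
#'
#' @param degree_cutoff minimum degree for a node to receive a weight.
#' @param node_score_cutoff fraction in [0, 1]; a neighbor joins a complex
#'   when its weight is at least \code{seed weight * (1 - cutoff)}.
#' @param k_core minimum core level a neighborhood must reach to score.
#' @param max_depth breadth-first expansion depth limit from the seed.
#' @param haircut drop complex members with fewer than 2 intra-complex
#'   connections.
#' @param fluff add boundary nodes whose neighborhood density exceeds
#'   \code{fluff_density_cutoff} (fluffed complexes may overlap).
#' @param fluff_density_cutoff density threshold for fluff.
#' @return List of validated parameters (class \code{mcode_params}).
#' @export
mcode_params <- function(degree_cutoff = 2, node_score_cutoff = 0.2,
                         k_core = 2, max_depth = 100, haircut = TRUE,
                         fluff = FALSE, fluff_density_cutoff = 0.1) {
  if (node_score_cutoff < 0 || node_score_cutoff > 1)
    stop("node_score_cutoff must lie in [0, 1]")
  if (degree_cutoff < 1 || k_core < 1 || max_depth < 1)
    stop("degree_cutoff, k_core and max_depth must be >= 1")
  structure(list(degree_cutoff = degree_cutoff,
                 node_score_cutoff = node_score_cutoff, k_core = k_core,
                 max_depth = max_depth, haircut = haircut, fluff = fluff,
                 fluff_density_cutoff = fluff_density_cutoff),
            class = "mcode_params")
}

graph_density <- function(n, m) {
  if (n < 2) return(0)
  2 * m / (n * (n - 1))
}

#' MCODE vertex weights
#'
#' The weight of a node with degree at or above the degree cutoff is the
#' highest core level reached inside its closed neighborhood (the node
#' plus its direct neighbors) multiplied by the edge density of that
#' neighborhood subgraph. Neighborhoods that do not reach the
#' \code{k_core} level (default 2) score 0, as do nodes below the degree
#' cutoff — such nodes neither seed complexes nor join them.
#'
#' @param graph simple undirected igraph graph with named vertices.
#' @param params \code{\link{mcode_params}}.
#' @return Named numeric vector of weights.
#' @export
vertex_weights <- function(graph, params = mcode_params()) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::vcount(graph) == 0)
    return(setNames(numeric(0), character(0)))
  nm <- igraph::V(graph)$name
  if (is.null(nm)) stop("graph vertices must be named")
  w <- setNames(numeric(length(nm)), nm)
  deg <- igraph::degree(graph)
  adj <- igraph::adjacent_vertices(graph, igraph::V(graph))
  for (i in seq_along(nm)) {
    if (deg[i] < params$degree_cutoff) next
    nbhd <- c(igraph::V(graph)[i], adj[[i]])
    sub <- igraph::induced_subgraph(graph, nbhd)
    kmax <- max(igraph::coreness(sub))
    if (kmax < params$k_core) next
    w[i] <- kmax * graph_density(igraph::vcount(sub), igraph::ecount(sub))
  }
  w
}

#' Score of a complex: subgraph density times size
#'
#' @param graph the host graph.
#' @param members character vector of at least 2 member node ids.
#' @return Edge density of the induced subgraph multiplied by the member
#'   count.
#' @export
complex_score <- function(graph, members) {
  if (length(members) < 2) stop("a complex needs at least 2 members")
  sub <- igraph::induced_subgraph(graph, members)
  graph_density(igraph::vcount(sub), igraph::ecount(sub)) *
    igraph::vcount(sub)
}

#' Detect dense complexes (MCODE)
#'
#' Unassigned nodes are taken as seeds in decreasing weight order (ties
#' lexicographic by id; zero-weight nodes never seed). From each seed a
#' breadth-first expansion adds unassigned neighbors whose weight is at
#' least \code{seed weight * (1 - node_score_cutoff)} (each node examined
#' once per complex, assigned to at most one complex, depth limited by
#' \code{max_depth}). Haircut then removes members with fewer than 2
#' intra-complex connections; fluff (off by default) adds boundary nodes
#' with dense neighborhoods and may create overlap between complexes.
#' Complexes with fewer than 2 members are discarded.
#'
#' @param graph simple undirected igraph graph with named vertices.
#' @param params \code{\link{mcode_params}}.
#' @return List of complexes sorted by score (descending; ties broken by
#'   size then seed id). Each element has \code{id}, \code{members}
#'   (sorted ids), \code{seed} and \code{score}.
#' @export
find_complexes <- function(graph, params = mcode_params()) {
  stopifnot(igraph::is_igraph(graph))
  n <- igraph::vcount(graph)
  if (n == 0) return(list())
  w <- vertex_weights(graph, params)
  nm <- names(w)
  adj <- lapply(igraph::adjacent_vertices(graph, igraph::V(graph)),
                function(v) v$name)
  names(adj) <- nm
  order_seeds <- nm[order(-w, nm)]
  assigned <- setNames(rep(FALSE, n), nm)
  complexes <- list()
  for (seed in order_seeds) {
    if (assigned[seed] || w[seed] <= 0) next
    threshold <- w[seed] * (1 - params$node_score_cutoff)
    members <- seed
    examined <- setNames(rep(FALSE, n), nm)
    examined[seed] <- TRUE
    frontier <- seed
    depth <- 0
    while (length(frontier) > 0 && depth < params$max_depth) {
      nxt <- character()
      for (v in frontier) {
        for (u in adj[[v]]) {
          if (examined[u] || assigned[u]) next
          examined[u] <- TRUE
          if (w[u] > 0 && w[u] >= threshold) {
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1
    }
    assigned[members] <- TRUE
    if (params$haircut) members <- haircut_members(graph, members)
    if (params$fluff)
      members <- fluff_members(graph, members, w, params)
    if (length(members) < 2) next
    if (!seed %in% members)  # haircut removed it; promote the densest member
      seed <- members[order(-w[members], members)][1]
    complexes[[length(complexes) + 1]] <-
      list(members = sort(members), seed = seed,
           score = complex_score(graph, members))
  }
  if (length(complexes) == 0) return(list())
  scores <- vapply(complexes, `[[`, 0, "score")
  sizes <- vapply(complexes, function(cm) length(cm$members), 0L)
  seeds <- vapply(complexes, `[[`, "", "seed")
  ord <- order(-scores, -sizes, seeds)
  complexes <- complexes[ord]
  for (i in seq_along(complexes)) complexes[[i]]$id <- i
  complexes
}

# iterated to a fixpoint so every surviving member keeps >= 2
# intra-complex connections after removals
haircut_members <- function(graph, members) {
  repeat {
    if (length(members) < 2) return(members)
    sub <- igraph::induced_subgraph(graph, members)
    keep <- igraph::V(sub)$name[igraph::degree(sub) >= 2]
    if (length(keep) == length(members)) return(members)
    members <- keep
  }
}

fluff_members <- function(graph, members, w, params) {
  if (length(members) == 0) return(members)
  boundary <- setdiff(
    unique(unlist(lapply(
      igraph::adjacent_vertices(graph, members), function(v) v$name))),
    members)
  add <- character()
  for (u in boundary) {
    nbhd <- c(u, igraph::neighbors(graph, u)$name)
    sub <- igraph::induced_subgraph(graph, nbhd)
    if (graph_density(igraph::vcount(sub), igraph::ecount(sub)) >
        params$fluff_density_cutoff)
      add <- c(add, u)
  }
  c(members, add)
}
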