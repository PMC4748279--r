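#' Run the full ceRNA annotation pipeline on synthetic data
#'
#' Generates a synthetic dataset from \code{cfg}, then runs every stage:
#' candidate ceRNA pairs (shared-regulator test), network assembly
#' (positive Spearman confirmation over the stress samples), MCODE
#' community detection, community and lincRNA GO annotation, per-time
#' point differential expression, hub selection, key-lincRNA selection,
#' and hierarchical clustering of the stress samples on the key lincRNAs.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param params \code{\link{mcode_params}}.
#' @param alpha_overlap,alpha_corr,alpha_enrich significance thresholds
#'   of the overlap, correlation and enrichment tests.
#' @param fdr_threshold DE significance threshold.
#' @param hub_fraction hub fraction of \code{\link{hub_threshold}}.
#' @return List with the generated inputs (\code{truth},
#'   \code{expression}, \code{go}), the per-stage outputs
#'   (\code{candidates}, \code{network}, \code{communities},
#'   \code{community_annotations}, \code{linc_annotations}, \code{de},
#'   \code{hubs}, \code{key_report}, \code{clustering}) and the
#'   ground-truth recovery \code{metrics} (see
#'   \code{\link{evaluate_recovery}}).
#' @export
run_pipeline <- function(cfg = sim_config(), params = mcode_params(),
                         alpha_overlap = 0.05, alpha_corr = 0.05,
                         alpha_enrich = 0.05, fdr_threshold = 0.05,
                         hub_fraction = 0.2) {
  tm <- simulate_target_map(cfg)
  expr <- simulate_expression(cfg, tm$truth)
  go <- simulate_go_annotations(cfg, tm$truth)
  stress_filter <- function(meta) meta$condition == cfg$conditions[2]
  cand <- candidate_pairs(tm$targets, alpha_overlap = alpha_overlap)
  net <- build_network(cand, expr, stress_filter, alpha_corr = alpha_corr)
  comms <- find_complexes(net, params)
  comm_ann <- annotate_communities(comms, net, go, alpha = alpha_enrich)
  linc_ann <- annotate_lincrnas(net, comms, comm_ann, go,
                                alpha = alpha_enrich)
  de <- simple_de(expr, cfg$conditions)
  hubs <- hub_threshold(net, hub_fraction)
  key <- select_key_lincrnas(net, hubs, de, linc_ann,
                             fdr_threshold = fdr_threshold,
                             tissue = cfg$tissue)
  clustering <- if (nrow(key$lincrnas) >= 1)
    tryCatch(cluster_samples(expr, key$lincrnas$lincrna, stress_filter),
             error = function(e) NULL) else NULL
  res <- list(truth = tm$truth, targets = tm$targets, expression = expr,
              go = go, candidates = cand, network = net,
              communities = comms, community_annotations = comm_ann,
              linc_annotations = linc_ann, de = de, hubs = hubs,
              key_report = key, clustering = clustering)
  res$metrics <- evaluate_recovery(res)
  res
}

planted_pairs <- function(truth) {
  do.call(rbind, lapply(truth$modules, function(mod) {
    pairs <- t(combn(sort(mod$members), 2))
    data.frame(rna_a = pairs[, 1], rna_b = pairs[, 2])
  }))
}

#' Ground-truth recovery metrics of a pipeline run
#'
#' Compares a \code{\link{run_pipeline}} result against its planted
#' truth:
#' \describe{
#'   \item{edge_recall / edge_precision / edge_f1}{recovered vs planted
#'     within-module RNA pairs, treating every unordered within-module
#'     pair as a planted edge.}
#'   \item{linc_go_recall}{fraction of planted module lincRNAs annotated
#'     (any tier) with their own module's GO term.}
#'   \item{tier1_decoy_rate}{fraction of community-tier annotations
#'     carrying a decoy term (should be 0).}
#'   \item{community_go_accuracy}{fraction of communities dominated by
#'     one planted module that are annotated with that module's term.}
#'   \item{key_linc_recall}{fraction of planted DE lincRNAs reported as
#'     key lincRNAs.}
#'   \item{early_late_accuracy}{agreement (best over label swap) between
#'     the 2-group sample clustering and the early/late split of the
#'     stress time course.}
#' }
#'
#' @param res result list from \code{\link{run_pipeline}}.
#' @return Named list of metrics.
#' @export
evaluate_recovery <- function(res) {
  truth <- res$truth
  cfg <- truth$cfg
  planted <- planted_pairs(truth)
  planted_key <- paste(planted$rna_a, planted$rna_b)
  el <- igraph::as_edgelist(res$network)
  edge_key <- apply(el, 1, function(e) paste(sort(e), collapse = " "))
  tp <- sum(edge_key %in% planted_key)
  recall <- if (length(planted_key) > 0) tp / length(planted_key) else NA
  precision <- if (length(edge_key) > 0) tp / length(edge_key) else NA
  f1 <- if (isTRUE(tp > 0)) 2 * precision * recall / (precision + recall)
        else 0
  # lincRNA annotation vs planted module terms
  module_term <- unlist(lapply(truth$modules, function(m)
    setNames(rep(m$go_id, length(m$lincs)), m$lincs)))
  ann <- res$linc_annotations
  got <- setNames(ann$go_id, ann$lincrna)
  linc_go_recall <- mean(!is.na(got[names(module_term)]) &
                           got[names(module_term)] == module_term)
  tier1 <- ann[ann$tier == "community", , drop = FALSE]
  tier1_decoy_rate <- if (nrow(tier1) > 0)
    mean(grepl("^GO:2", tier1$go_id)) else NA_real_
  # community annotation vs dominant planted module
  comm_acc <- NA_real_
  if (length(res$communities) > 0) {
    member_module <- setNames(
      rep(vapply(truth$modules, `[[`, 0L, "id"),
          vapply(truth$modules, function(m) length(m$members), 0L)),
      unlist(lapply(truth$modules, `[[`, "members")))
    hits <- vapply(res$communities, function(cm) {
      mods <- member_module[cm$members]
      mods <- mods[!is.na(mods)]
      if (length(mods) < length(cm$members) / 2) return(NA)
      dom <- as.integer(names(sort(table(mods), decreasing = TRUE))[1])
      ca <- res$community_annotations
      row <- ca[ca$community == cm$id, ]
      isTRUE(row$annotated) &&
        identical(row$go_id, truth$modules[[dom]]$go_id)
    }, NA)
    if (any(!is.na(hits))) comm_acc <- mean(hits[!is.na(hits)])
  }
  key_recall <- if (length(truth$de_lincrnas) > 0)
    mean(truth$de_lincrnas %in% res$key_report$lincrnas$lincrna)
  else NA_real_
  early_late <- NA_real_
  if (!is.null(res$clustering)) {
    meta <- res$expression$samples
    stress <- meta[meta$condition == cfg$conditions[2], ]
    tp_idx <- match(stress$timepoint,
                    canonical_timepoints(cfg$n_timepoints)$timepoint)
    late <- as.integer(tp_idx >= cfg$late_start_index) + 1L
    grp <- res$clustering$groups[stress$sample]
    acc <- mean(grp == late)
    early_late <- max(acc, 1 - acc)
  }
  list(edge_recall = recall, edge_precision = precision, edge_f1 = f1,
       linc_go_recall = linc_go_recall, tier1_decoy_rate = tier1_decoy_rate,
       community_go_accuracy = comm_acc, key_linc_recall = key_recall,
       early_late_accuracy = early_late)
}
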