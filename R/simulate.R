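# Synthetic-data generator with planted ground truth. It emulates the
# study design the pipeline targets: a 9-time-point x 3-replicate x
# 2-condition (Pi-sufficient vs Pi-starved) expression experiment, blocks
# of RNAs ("modules") sharing miRNA regulator sets and a common latent
# activity that makes them positively co-expressed, block-specific GO
# labels on genes, and late-stage up-regulation of responsive lincRNAs.

canonical_timepoints <- function(n) {
  if (n == 9) {
    data.frame(timepoint = c("1h", "6h", "24h", "3d", "7d", "21d",
                             "21d+1h", "21d+6h", "21d+24h"),
               hours = c(1, 6, 24, 72, 168, 504, 505, 510, 528))
  } else {
    data.frame(timepoint = sprintf("tp%02d", seq_len(n)),
               hours = 24 * seq_len(n))
  }
}

#' Simulation configuration
#'
#' All knobs of the synthetic-data generator, validated against the
#' generator's invariants. The defaults define the package's recovery
#' configuration: 6 planted modules of 8 RNAs (2 lincRNAs + 6 genes each)
#' sharing 4 miRNAs per module inside a universe of 60 miRNAs, low
#' background targeting, the 9-time-point / 3-replicate / 2-condition
#' design (so 27 stress samples per tissue), moderate noise against a
#' strong shared module activity, and a 2-unit log2 up-shift of
#' responsive lincRNAs from the 7-day time point onwards.
#'
#' @param n_mirnas,n_genes,n_lincrnas pool sizes.
#' @param n_modules,module_size,lincs_per_module planted-module layout;
#'   each module holds \code{lincs_per_module} lincRNAs (>= 1) and the
#'   rest genes (>= 2).
#' @param mirnas_per_module shared miRNA regulators per module.
#' @param background_target_prob probability of an off-module
#'   miRNA-to-RNA edge.
#' @param n_timepoints,n_replicates,conditions,tissue design layout; with
#'   9 time points the canonical labels (1h ... 21d+24h) are used.
#' @param noise_sd Gaussian noise on log2 expression.
#' @param module_activity_sd standard deviation of the shared per-module
#'   latent activity (drawn per condition x time point, shared by
#'   replicates).
#' @param de_effect log2 up-shift applied to responsive lincRNAs in
#'   stressed samples at time points >= \code{late_start_index}.
#' @param late_start_index first "late" time point (default 5, the 7-day
#'   position of the canonical design).
#' @param responsive_fraction fraction of modules whose lincRNAs are
#'   planted as differentially expressed (default all).
#' @param n_decoy_terms,decoy_prob decoy GO vocabulary for background
#'   genes.
#' @param seed integer master seed; each generated table derives its own
#'   sub-stream from it.
#' @return Validated configuration list (class \code{sim_config}).
#' @export
sim_config <- function(n_mirnas = 60, n_genes = 90, n_lincrnas = 30,
                       n_modules = 6, module_size = 8,
                       lincs_per_module = 2, mirnas_per_module = 4,
                       background_target_prob = 0.02, n_timepoints = 9,
                       n_replicates = 3,
                       conditions = c("control", "starved"),
                       tissue = "root", noise_sd = 0.3,
                       module_activity_sd = 0.5, de_effect = 2,
                       late_start_index = 5, responsive_fraction = 1,
                       n_decoy_terms = 20, decoy_prob = 0.8, seed = 1) {
  cfg <- list(n_mirnas = n_mirnas, n_genes = n_genes,
              n_lincrnas = n_lincrnas, n_modules = n_modules,
              module_size = module_size,
              lincs_per_module = lincs_per_module,
              mirnas_per_module = mirnas_per_module,
              background_target_prob = background_target_prob,
              n_timepoints = n_timepoints, n_replicates = n_replicates,
              conditions = conditions, tissue = tissue,
              noise_sd = noise_sd, module_activity_sd = module_activity_sd,
              de_effect = de_effect, late_start_index = late_start_index,
              responsive_fraction = responsive_fraction,
              n_decoy_terms = n_decoy_terms, decoy_prob = decoy_prob,
              seed = as.integer(seed))
  counts <- cfg[c("n_mirnas", "n_genes", "n_lincrnas", "n_modules",
                  "module_size", "lincs_per_module", "mirnas_per_module",
                  "n_timepoints", "n_replicates")]
  if (any(unlist(counts) < 1))
    stop("configuration error: all counts must be positive")
  if (n_modules * module_size > n_genes + n_lincrnas)
    stop("configuration error: n_modules * module_size must not exceed ",
         "n_genes + n_lincrnas")
  if (mirnas_per_module * n_modules > n_mirnas)
    stop("configuration error: mirnas_per_module * n_modules must not ",
         "exceed n_mirnas")
  if (background_target_prob < 0 || background_target_prob > 1)
    stop("configuration error: background_target_prob must lie in [0,1]")
  if (decoy_prob < 0 || decoy_prob > 1 ||
      responsive_fraction < 0 || responsive_fraction > 1)
    stop("configuration error: probabilities must lie in [0,1]")
  if (noise_sd < 0 || module_activity_sd < 0 || de_effect < 0)
    stop("configuration error: noise_sd, module_activity_sd and de_effect ",
         "must be >= 0")
  if (length(conditions) != 2 || anyDuplicated(conditions))
    stop("configuration error: conditions must be two distinct labels")
  if (late_start_index < 1 || late_start_index > n_timepoints)
    stop("configuration error: late_start_index must index a time point")
  if (lincs_per_module + 2 > module_size)
    stop("configuration error: each module needs at least 2 genes")
  if (lincs_per_module * n_modules > n_lincrnas)
    stop("configuration error: not enough lincRNAs for the planted modules")
  if (n_modules * (module_size - lincs_per_module) > n_genes)
    stop("configuration error: not enough genes for the planted modules")
  structure(cfg, class = "sim_config")
}

sim_seed <- function(cfg, stream) {
  # deterministic per-table sub-stream; adding a table never perturbs others
  set.seed((cfg$seed * 131L + stream) %% .Machine$integer.max)
}

rna_ids <- function(cfg) {
  list(genes = sprintf("gene%04d", seq_len(cfg$n_genes)),
       lincs = sprintf("linc%04d", seq_len(cfg$n_lincrnas)))
}

#' Simulate a miRNA-target map with planted ceRNA modules
#'
#' Every RNA of a planted module is targeted by all of that module's
#' shared miRNAs; every other miRNA-to-RNA edge is drawn independently
#' with probability \code{background_target_prob}. The same configuration
#' (including seed) always yields identical output.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return List with \code{targets} (a \code{\link{target_map}}) and
#'   \code{truth}, the planted ground truth: per-module member/miRNA/GO
#'   assignments with responsive flags, the set of planted DE lincRNAs,
#'   and the generating configuration.
#' @export
simulate_target_map <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ids <- rna_ids(cfg)
  mirnas <- sprintf("mir%04d", seq_len(cfg$n_mirnas))
  modules <- list()
  n_resp <- round(cfg$responsive_fraction * cfg$n_modules)
  for (m in seq_len(cfg$n_modules)) {
    lincs <- ids$lincs[(m - 1) * cfg$lincs_per_module +
                         seq_len(cfg$lincs_per_module)]
    n_g <- cfg$module_size - cfg$lincs_per_module
    genes <- ids$genes[(m - 1) * n_g + seq_len(n_g)]
    modules[[m]] <- list(
      id = m, members = c(genes, lincs), genes = genes, lincs = lincs,
      mirnas = mirnas[(m - 1) * cfg$mirnas_per_module +
                        seq_len(cfg$mirnas_per_module)],
      go_id = sprintf("GO:1%06d", m),
      go_name = sprintf("planted process %d", m),
      responsive = m <= n_resp)
  }
  all_rnas <- c(ids$genes, ids$lincs)
  planted <- matrix(FALSE, cfg$n_mirnas, length(all_rnas),
                    dimnames = list(mirnas, all_rnas))
  for (mod in modules) planted[mod$mirnas, mod$members] <- TRUE
  sim_seed(cfg, 1L)
  background <- matrix(
    runif(cfg$n_mirnas * length(all_rnas)) < cfg$background_target_prob,
    cfg$n_mirnas, length(all_rnas), dimnames = dimnames(planted))
  edge <- planted | (background & !planted)
  targets <- apply(edge, 1, function(row) colnames(edge)[row],
                   simplify = FALSE)
  truth <- structure(
    list(modules = modules,
         de_lincrnas = sort(unlist(lapply(
           modules[vapply(modules, `[[`, TRUE, "responsive")], `[[`,
           "lincs"))),
         cfg = cfg),
    class = "planted_truth")
  list(targets = target_map(targets), truth = truth)
}

check_truth <- function(cfg, truth) {
  if (!inherits(truth, "planted_truth") || !identical(truth$cfg, cfg))
    stop("configuration error: truth was not generated from this config")
}

#' Simulate an expression matrix over the planted design
#'
#' Log2 expression is additive: an RNA baseline, a shared per-module
#' latent activity, and Gaussian noise. The activity is an AR(1)
#' trajectory over time points (autocorrelation 0.7, stationary standard
#' deviation \code{module_activity_sd}) per module, shared by replicates
#' and by both conditions — time-driven co-regulation common to both
#' arms, which makes within-module pairs positively rank-correlated
#' across the stress samples with the smoothness of a real time course,
#' while keeping the planted response the only systematic
#' condition difference (so differential-expression nulls are clean when
#' \code{de_effect = 0}). Responsive modules respond to the stress as
#' coherent units: from \code{late_start_index} onwards, every member of
#' a responsive module — genes and lincRNAs alike — is up-shifted in
#' stressed samples by a module-level amount (\code{de_effect} times a
#' per-module Uniform(0.5, 1.5) multiplier, i.e. \code{de_effect} on
#' average). Shifting the whole module together is what the ceRNA
#' hypothesis itself predicts (competing partners co-respond), keeps
#' responsive lincRNAs co-expressed with their partner genes, and the
#' heterogeneity of the shift across modules is what lets
#' correlation-distance sample clustering tell early from late stress
#' stages (a shift uniform across all features would cancel out of
#' centered correlations). Values are exponentiated to an RPKM-like
#' non-negative scale.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param truth planted truth from \code{\link{simulate_target_map}}.
#' @return An \code{\link{expression_matrix}} covering every gene and
#'   lincRNA of the configuration.
#' @export
simulate_expression <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  check_truth(cfg, truth)
  ids <- rna_ids(cfg)
  all_rnas <- c(ids$genes, ids$lincs)
  tp <- canonical_timepoints(cfg$n_timepoints)
  samples <- expand.grid(replicate = seq_len(cfg$n_replicates),
                         tp_index = seq_len(cfg$n_timepoints),
                         condition = cfg$conditions,
                         stringsAsFactors = FALSE)
  samples$timepoint <- tp$timepoint[samples$tp_index]
  samples$hours <- tp$hours[samples$tp_index]
  samples$tissue <- cfg$tissue
  samples$sample <- sprintf("%s_%s_tp%02d_r%d", samples$tissue,
                            samples$condition, samples$tp_index,
                            samples$replicate)
  sim_seed(cfg, 2L)
  baseline <- rnorm(length(all_rnas), mean = 3, sd = 1)
  names(baseline) <- all_rnas
  # shared latent activity per (module, time point): an AR(1) trajectory
  # (autocorrelation 0.7, stationary sd = module_activity_sd) shared by
  # replicates AND conditions — time-driven co-regulation is common to
  # both arms, so the only systematic condition difference is the
  # planted stress response
  phi <- 0.7
  activity <- matrix(NA_real_, cfg$n_modules, cfg$n_timepoints)
  activity[, 1] <- rnorm(cfg$n_modules, sd = cfg$module_activity_sd)
  for (t in seq_len(cfg$n_timepoints)[-1])
    activity[, t] <- phi * activity[, t - 1] +
      sqrt(1 - phi^2) * rnorm(cfg$n_modules, sd = cfg$module_activity_sd)
  module_of <- setNames(rep(NA_integer_, length(all_rnas)), all_rnas)
  for (mod in truth$modules) module_of[mod$members] <- mod$id
  responsive <- setNames(rep(FALSE, length(all_rnas)), all_rnas)
  responsive[truth$de_lincrnas] <- TRUE
  # module-level late stress response, bounded away from zero for
  # responsive modules (a responsive module that does not respond would
  # contradict its own label); 0 for non-responsive modules
  module_shift <- cfg$de_effect * runif(cfg$n_modules, 0.5, 1.5) *
    vapply(truth$modules, `[[`, TRUE, "responsive")
  shift <- setNames(rep(0, length(all_rnas)), all_rnas)
  in_mod <- !is.na(module_of)
  shift[in_mod] <- module_shift[module_of[in_mod]]
  lmat <- matrix(baseline, nrow = length(all_rnas), ncol = nrow(samples),
                 dimnames = list(all_rnas, samples$sample))
  for (j in seq_len(nrow(samples))) {
    cond <- samples$condition[j]
    t_idx <- samples$tp_index[j]
    lmat[in_mod, j] <- lmat[in_mod, j] +
      activity[cbind(module_of[in_mod], t_idx)]
    if (cond == cfg$conditions[2] && t_idx >= cfg$late_start_index)
      lmat[, j] <- lmat[, j] + shift
  }
  lmat <- lmat + matrix(rnorm(length(lmat), sd = cfg$noise_sd),
                        nrow = nrow(lmat))
  types <- setNames(c(rep("gene", cfg$n_genes),
                      rep("lincRNA", cfg$n_lincrnas)), all_rnas)
  expression_matrix(2^lmat, types,
                    samples[, c("sample", "tissue", "condition",
                                "timepoint", "hours", "replicate")])
}

#' Simulate a gene -> GO annotation table for the planted modules
#'
#' Every gene of module m carries m's planted GO term; background genes
#' carry decoy terms (with probability \code{decoy_prob}, one or two
#' draws from the decoy vocabulary); lincRNAs carry no annotation, as the
#' enrichment universe consists of genes only.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param truth planted truth from \code{\link{simulate_target_map}}.
#' @return GO annotation data frame (\code{gene}, \code{go_id},
#'   \code{go_name}).
#' @export
simulate_go_annotations <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  check_truth(cfg, truth)
  ids <- rna_ids(cfg)
  rows <- lapply(truth$modules, function(mod)
    data.frame(gene = mod$genes, go_id = mod$go_id, go_name = mod$go_name))
  module_genes <- unlist(lapply(truth$modules, `[[`, "genes"))
  bg <- setdiff(ids$genes, module_genes)
  decoys <- sprintf("GO:2%06d", seq_len(cfg$n_decoy_terms))
  sim_seed(cfg, 3L)
  for (g in bg) {
    if (runif(1) >= cfg$decoy_prob) next
    k <- sample(1:2, 1)
    terms <- sample(decoys, k)
    rows[[length(rows) + 1]] <- data.frame(
      gene = g, go_id = terms,
      go_name = sprintf("decoy process %s", sub("GO:2", "", terms)))
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, c("gene", "go_id")]), ]
  rownames(out) <- NULL
  out
}

#' Simulate candidate-transcript attributes with expected filter outcomes
#'
#' Emits a table spanning every rejection reason of the lincRNA candidate
#' filter (too short, non-intergenic class, never expressed above the
#' RPKM floor, protein-similar, coding-potential-positive) plus clean
#' passers, including the boundary cases: length exactly 200 (kept), RPKM
#' exactly at the floor in a single sample (kept), and protein similarity
#' where only one arm of the coverage/e-value conjunction holds (kept).
#' Each transcript carries its expected label.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param n_random additional random transcripts beyond the deterministic
#'   boundary panel.
#' @return Data frame of transcript attributes with an \code{expected}
#'   label column (\code{"keep"} or \code{"reject: <reason>"}).
#' @export
simulate_candidate_transcripts <- function(cfg, n_random = 30) {
  stopifnot(inherits(cfg, "sim_config"))
  base <- function(id, length = 400, class_code = "u",
                   rpkm = c(2, 0.1, 0.3), coverage = NA, evalue = NA,
                   cpat = FALSE, cpc = FALSE)
    data.frame(transcript = id, length = length, class_code = class_code,
               rpkm_1 = rpkm[1], rpkm_2 = rpkm[2], rpkm_3 = rpkm[3],
               sim_coverage = coverage, sim_evalue = evalue,
               cpat_coding = cpat, cpc_coding = cpc)
  panel <- rbind(
    base("cand_keep_clean"),
    base("cand_keep_len200", length = 200),
    base("cand_keep_rpkm_floor", rpkm = c(0.5, 0.2, 0.1)),
    base("cand_keep_cov_only", coverage = 0.6, evalue = 1e-4),
    base("cand_keep_eval_only", coverage = 0.4, evalue = 1e-6),
    base("cand_rej_length", length = 150),
    base("cand_rej_class_i", class_code = "i"),
    base("cand_rej_class_x", class_code = "x"),
    base("cand_rej_expression", rpkm = c(0.4, 0.4, 0.4)),
    base("cand_rej_protein", coverage = 0.6, evalue = 1e-6),
    base("cand_rej_cpat", cpat = TRUE),
    base("cand_rej_cpc", cpc = TRUE),
    base("cand_rej_first_rule", length = 150, cpat = TRUE))
  sim_seed(cfg, 4L)
  if (n_random > 0) {
    rnd <- do.call(rbind, lapply(seq_len(n_random), function(i) {
      sim_hit <- runif(1) < 0.4
      base(sprintf("cand_rand_%03d", i),
           length = sample(c(120, 200, 350, 900, 2500), 1),
           class_code = sample(c("u", "u", "u", "i", "x"), 1),
           rpkm = round(runif(3, 0, 3), 2),
           coverage = if (sim_hit) round(runif(1), 2) else NA,
           evalue = if (sim_hit) 10^runif(1, -9, -2) else NA,
           cpat = runif(1) < 0.15, cpc = runif(1) < 0.15)
    }))
    panel <- rbind(panel, rnd)
  }
  panel$expected <- expected_filter_label(panel)
  rownames(panel) <- NULL
  panel
}

# ground-truth labeling: the filter conjunction spelled out rule by rule
expected_filter_label <- function(tab) {
  rpkm <- as.matrix(tab[, grep("^rpkm_", names(tab)), drop = FALSE])
  sim_rej <- !is.na(tab$sim_coverage) & !is.na(tab$sim_evalue) &
    tab$sim_coverage > 0.5 & tab$sim_evalue < 1e-5
  reason <- rep(NA_character_, nrow(tab))
  reason[is.na(reason) & tab$length < 200] <- "length"
  reason[is.na(reason) & tab$class_code != "u"] <- "class"
  reason[is.na(reason) & apply(rpkm, 1, max) < 0.5] <- "expression"
  reason[is.na(reason) & sim_rej] <- "protein_similarity"
  reason[is.na(reason) & (tab$cpat_coding | tab$cpc_coding)] <-
    "coding_potential"
  ifelse(is.na(reason), "keep", paste0("reject: ", reason))
}

#' Write a complete synthetic fixture directory
#'
#' Generates every table of the design (targets, expression + metadata +
#' types, GO annotations, DE calls from \code{\link{simple_de}}, candidate
#' transcripts) and a YAML truth file, using the I/O formats of the
#' package.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the list of generated objects.
#' @export
simulate_dataset <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tm <- simulate_target_map(cfg)
  expr <- simulate_expression(cfg, tm$truth)
  go <- simulate_go_annotations(cfg, tm$truth)
  cand <- simulate_candidate_transcripts(cfg)
  de <- simple_de(expr, cfg$conditions)
  write_target_table(tm$targets, file.path(dir, "targets.tsv"))
  write_expression(expr, file.path(dir, "expression.tsv"),
                   file.path(dir, "samples.tsv"))
  write_go_table(go, file.path(dir, "go.tsv"))
  write_de_table(de, file.path(dir, "de.tsv"))
  write_tsv(cand, file.path(dir, "candidates.tsv"))
  truth <- tm$truth
  yaml::write_yaml(
    list(modules = lapply(truth$modules, function(m)
      m[c("id", "members", "genes", "lincs", "mirnas", "go_id",
          "responsive")]),
      de_lincrnas = truth$de_lincrnas),
    file.path(dir, "truth.yaml"))
  invisible(list(targets = tm$targets, truth = truth, expression = expr,
                 go = go, candidates = cand, de = de))
}
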