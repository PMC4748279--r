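test_that("hub selection takes the top fifth, keeping boundary ties", {
  deg <- setNames(1:10, paste0("n", 1:10))
  hubs <- hub_threshold(deg)
  expect_setequal(hubs$hubs, c("n9", "n10"))
  expect_equal(hubs$threshold, 8)
  # every node tied: all hubs, with a warning
  expect_warning(all_tied <- hub_threshold(setNames(rep(5, 10),
                                                    paste0("n", 1:10))),
                 "every node is a hub")
  expect_length(all_tied$hubs, 10)
  # boundary tie is included
  deg2 <- setNames(c(10, 9, 9, 9, 1, 1, 1, 1, 1, 1), paste0("m", 1:10))
  expect_setequal(hub_threshold(deg2)$hubs, c("m1", "m2", "m3", "m4"))
  # single node network
  single <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(single)$name <- "only"
  expect_equal(hub_threshold(single)$hubs, "only")
  expect_error(hub_threshold(igraph::make_empty_graph(0)), "empty")
  # igraph interface: hubs computed over all node degrees
  g <- igraph::make_graph(~ p1 - p2 - p3 - p4 - p5)
  h <- hub_threshold(g, 0.4)
  expect_setequal(h$hubs, c("p2", "p3", "p4"))  # boundary tie included
  expect_equal(h$threshold, 1)
  expect_true(all(igraph::degree(g)[h$hubs] > h$threshold))
})

test_that("key lincRNAs are DE hub lincRNAs, sorted by degree", {
  g <- igraph::make_graph(c("l1","g1", "l1","g2", "l1","g3",
                            "l2","g1", "l2","g2",
                            "l3","g1",
                            "g1","g2", "g1","g3", "g2","g3"),
                          directed = FALSE)
  igraph::V(g)$type <- ifelse(grepl("^l", igraph::V(g)$name),
                              "lincRNA", "gene")
  de <- data.frame(rna = c("l1", "l2", "l3", "g1"),
                   timepoint = "21d",
                   fdr = c(0.04, 0.06, 0.01, 0.001))
  hubs <- list(threshold = 1, hubs = c("l1", "l2", "g1", "g2"))
  ann <- data.frame(lincrna = "l1", go_id = "GO:9", go_name = "x",
                    tier = "community", p = 1e-4, community = 1L)
  rep <- select_key_lincrnas(g, hubs, de, ann, tissue = "root")
  # l1: hub + FDR 0.04 -> in; l2: hub but FDR 0.06 -> out; l3: DE, not hub
  expect_equal(rep$lincrnas$lincrna, "l1")
  expect_equal(rep$lincrnas$go_id, "GO:9")
  expect_equal(rep$tissue, "root")
  expect_equal(rep$threshold, 1)
})

test_that("key-set comparison is exact and symmetric in its common part", {
  a <- c("x1", "x2", "x3")
  b <- c("x2", "x3", "x4")
  cmp <- compare_key_sets(a, b)
  expect_equal(cmp$common, c("x2", "x3"))
  expect_equal(cmp$only_a, "x1")
  expect_equal(cmp$only_b, "x4")
  expect_equal(compare_key_sets(b, a)$common, cmp$common)
  expect_equal(compare_key_sets(a, a)$only_a, character(0))
  expect_length(compare_key_sets(a, "zz")$common, 0)
})

test_that("published root and shoot key-lincRNA tables share 11 identifiers", {
  root <- key_lincrna_table("root")
  shoot <- key_lincrna_table("shoot")
  expect_equal(nrow(root), 47)
  expect_equal(nrow(shoot), 40)
  expect_equal(anyDuplicated(root$lincrna), 0)
  expect_equal(anyDuplicated(shoot$lincrna), 0)
  cmp <- compare_key_sets(root$lincrna, shoot$lincrna)
  expect_length(cmp$common, 11)
})

make_cluster_expr <- function(vals, conditions = "starved") {
  n <- ncol(vals)
  samples <- data.frame(sample = colnames(vals), tissue = "root",
                        condition = conditions,
                        timepoint = paste0("t", seq_len(n)),
                        hours = seq_len(n), replicate = 1)
  expression_matrix(vals, setNames(rep("lincRNA", nrow(vals)),
                                   rownames(vals)), samples)
}

test_that("sample clustering recovers duplicated blocks and ignores order", {
  blockA <- matrix(rep(c(8, 1, 5, 2), 3), ncol = 3,
                   dimnames = list(paste0("f", 1:4), paste0("a", 1:3)))
  blockB <- matrix(rep(c(1, 9, 2, 7), 3), ncol = 3,
                   dimnames = list(paste0("f", 1:4), paste0("b", 1:3)))
  expr <- make_cluster_expr(cbind(blockA, blockB))
  cl <- cluster_samples(expr, paste0("f", 1:4))
  expect_length(unique(cl$groups[paste0("a", 1:3)]), 1)
  expect_length(unique(cl$groups[paste0("b", 1:3)]), 1)
  expect_true(cl$groups[["a1"]] != cl$groups[["b1"]])
  # permutation invariance of the partition
  perm <- c(4, 1, 6, 2, 5, 3)
  expr2 <- make_cluster_expr(cbind(blockA, blockB)[, perm])
  cl2 <- cluster_samples(expr2, paste0("f", 1:4))
  same <- outer(cl$groups, cl$groups, "==")
  same2 <- outer(cl2$groups, cl2$groups, "==")
  expect_equal(same2[rownames(same), colnames(same)], same)
  # degenerate input
  flat <- matrix(3, 2, 4, dimnames = list(c("f1", "f2"), paste0("s", 1:4)))
  expect_error(cluster_samples(make_cluster_expr(flat), c("f1", "f2")),
               "zero variance")
})

test_that("welch DE matches t.test and flags planted effects, not nulls", {
  cfg <- tiny_cfg(n_timepoints = 4, late_start_index = 3, seed = 31)
  tm <- simulate_target_map(cfg)
  expr <- simulate_expression(cfg, tm$truth)
  de <- simple_de(expr)
  # cross-check a handful of rows against stats::t.test
  lv <- log2(expr$values + 1)
  meta <- expr$samples
  for (rna in c("gene0001", "linc0001", "gene0020")) {
    for (tp in unique(meta$timepoint)[c(1, 4)]) {
      i1 <- meta$timepoint == tp & meta$condition == "control"
      i2 <- meta$timepoint == tp & meta$condition == "starved"
      ref <- t.test(lv[rna, i1], lv[rna, i2])$p.value
      got <- de[de$rna == rna & de$timepoint == tp, ]
      expect_equal(got$p, ref, tolerance = 1e-10)
    }
  }
  # identical replicate values across conditions -> p = fdr = 1
  flat_vals <- matrix(2, 3, 6,
                      dimnames = list(paste0("r", 1:3), paste0("s", 1:6)))
  flat_meta <- data.frame(sample = paste0("s", 1:6), tissue = "root",
                          condition = rep(c("control", "starved"), each = 3),
                          timepoint = "1h", hours = 1,
                          replicate = rep(1:3, 2))
  flat <- expression_matrix(flat_vals,
                            setNames(rep("gene", 3), paste0("r", 1:3)),
                            flat_meta)
  de_flat <- simple_de(flat)
  expect_true(all(de_flat$fdr == 1))
  expect_error(simple_de(flat, timepoints = "6h"), ">= 2 replicates")
})

test_that("null data yields nominal raw significance and controlled FDR", {
  raw <- fdr <- numeric(50)
  for (s in 1:50) {
    cfg <- tiny_cfg(n_timepoints = 2, late_start_index = 1, de_effect = 0,
                    seed = 1000 + s)
    tm <- simulate_target_map(cfg)
    expr <- simulate_expression(cfg, tm$truth)
    de <- simple_de(expr)
    raw[s] <- mean(de$p < 0.05)
    fdr[s] <- mean(de$fdr < 0.05)
  }
  expect_lt(abs(mean(raw) - 0.05), 0.02)
  expect_lte(mean(fdr), 0.05)
})

test_that("planted responsive lincRNAs are recovered as differentially expressed", {
  rec <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = 2000 + s)
    tm <- simulate_target_map(cfg)
    expr <- simulate_expression(cfg, tm$truth)
    de <- simple_de(expr)
    flagged <- unique(de$rna[de$fdr < 0.05])
    mean(tm$truth$de_lincrnas %in% flagged)
  }, 0)
  expect_gte(mean(rec), 0.9)
})
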