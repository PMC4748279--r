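test_that("hypergeometric upper tail matches closed forms and enumeration", {
  expect_equal(hypergeom_upper_tail(0, 5, 7, 100), 1)
  expect_equal(hypergeom_upper_tail(3, 3, 3, 3), 1)
  # C(3,2)C(7,2) + C(3,3)C(7,1) over C(10,4) = 70/210
  expect_equal(hypergeom_upper_tail(2, 3, 4, 10), 1 / 3, tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(2, 3, 4, 10),
               enum_hyper_tail(2, 3, 4, 10), tolerance = 1e-12)
  # spot-check enumeration agreement on a grid of small universes
  for (U in c(5, 8, 10)) {
    for (M in c(1, 3, U)) {
      for (N in c(2, U - 1)) {
        expect_equal(hypergeom_upper_tail(0:min(M, N), M, N, U),
                     enum_hyper_tail_all(M, N, U), tolerance = 1e-12)
      }
    }
  }
})

test_that("hypergeometric tail is monotone in n and validates inputs", {
  set.seed(42)
  for (i in 1:200) {
    U <- sample(2:5000, 1)
    M <- sample(1:U, 1)
    N <- sample(1:U, 1)
    p <- hypergeom_upper_tail(0:min(M, N), M, N, U)
    expect_true(all(diff(p) <= 1e-12))
  }
  expect_error(hypergeom_upper_tail(1, 3, 4, 0), "universe")
  expect_error(hypergeom_upper_tail(5, 3, 4, 10), "overlap")
  expect_error(hypergeom_upper_tail(1, 11, 4, 10), "exceed")
})

test_that("candidate_pairs selects significant regulator overlaps", {
  shared <- paste0("mir", 1:5)
  tm <- target_map(c(
    setNames(lapply(shared, function(m) c("rnaA", "rnaB")), shared),
    setNames(lapply(paste0("bg", 1:95), function(m) "rnaC"),
             paste0("bg", 1:95))))
  expect_equal(mirna_universe_size(tm), 100)
  pairs <- candidate_pairs(tm)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$rna_a, "rnaA")
  expect_equal(pairs$p_overlap, 1 / choose(100, 5), tolerance = 1e-12)
  # disjoint regulator sets: P(X >= 0) = 1, never selected
  tm2 <- target_map(list(m1 = "x", m2 = "y", m3 = c("x", "z"),
                         m4 = "w", m5 = "q"))
  p2 <- candidate_pairs(tm2, rnas = c("y", "w"))
  expect_equal(nrow(p2), 0)
})

test_that("candidate_pairs is equivariant under RNA relabeling", {
  cfg <- tiny_cfg(background_target_prob = 0.1, seed = 9)
  tm <- simulate_target_map(cfg)$targets
  pairs <- candidate_pairs(tm)
  perm <- function(x) chartr("gl", "GL", x)  # injective relabeling
  tm_perm <- target_map(lapply(tm$targets, perm))
  pairs_perm <- candidate_pairs(tm_perm)
  key <- function(df, f = identity)
    sort(paste(pmin(f(df$rna_a), f(df$rna_b)),
               pmax(f(df$rna_a), f(df$rna_b))))
  expect_equal(key(pairs_perm), key(pairs, perm))
  expect_equal(sort(pairs_perm$p_overlap), sort(pairs$p_overlap))
})

test_that("candidate_pairs excludes regulator-free RNAs and empty universes", {
  tm <- target_map(list(m1 = c("a", "b")))
  expect_message(res <- candidate_pairs(tm, rnas = c("a", "b", "c")),
                 "without miRNA regulators")
  expect_true(all(c(res$rna_a, res$rna_b) %in% c("a", "b")))
  expect_error(candidate_pairs(target_map(list())), "empty miRNA universe")
})

test_that("spearman_with_p matches the mean-rank oracle and cor.test", {
  expect_equal(spearman_with_p(1:5, c(10, 20, 30, 40, 50))$rho, 1)
  expect_equal(spearman_with_p(1:5, c(10, 20, 30, 40, 50))$p, 0)
  expect_equal(spearman_with_p(1:5, c(50, 40, 30, 20, 10))$rho, -1)
  # ties: mean ranks, Pearson on ranks
  x <- c(1, 2, 2, 4); y <- c(3, 5, 4, 8)
  expect_equal(spearman_with_p(x, y)$rho, naive_spearman(x, y))
  set.seed(7)
  for (i in 1:20) {
    x <- sample(1:8, 12, replace = TRUE)
    y <- x + rnorm(12, sd = 2)
    got <- spearman_with_p(x, y)
    ref <- suppressWarnings(
      cor.test(x, y, method = "spearman", exact = FALSE))
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
  expect_error(spearman_with_p(1:2, 1:2), "at least 3")
  expect_false(spearman_with_p(rep(1, 5), 1:5)$defined)
})

test_that("build_network keeps positively correlated significant pairs only", {
  n_samp <- 12
  samples <- data.frame(sample = paste0("s", 1:n_samp), tissue = "root",
                        condition = "starved",
                        timepoint = paste0("t", rep(1:(n_samp / 3), each = 3)),
                        hours = rep(seq_len(n_samp / 3) * 24, each = 3),
                        replicate = rep(1:3, n_samp / 3))
  base <- seq_len(n_samp)
  vals <- rbind(a = base, b = base + 0.5, c = rev(base), d = rep(2, n_samp))
  colnames(vals) <- samples$sample
  types <- setNames(c("gene", "lincRNA", "gene", "gene"), rownames(vals))
  expr <- expression_matrix(vals, types, samples)
  cand <- data.frame(rna_a = c("a", "a", "a"), rna_b = c("b", "c", "d"),
                     shared_count = 3L, m = 3L, n = 3L, p_overlap = 0.001)
  expect_message(net <- build_network(cand, expr), "zero-variance")
  expect_equal(sort(igraph::V(net)$name), c("a", "b"))
  expect_equal(igraph::ecount(net), 1)
  expect_true(igraph::E(net)$rho > 0)
  expect_silent(validate_network(net))
  # no candidates -> empty network; too few samples -> error
  expect_equal(igraph::vcount(build_network(cand[0, ], expr)), 0)
  expect_error(build_network(cand, expr,
                             function(m) m$sample %in% c("s1", "s2")),
               "at least 3 samples")
})

test_that("average degree and power-law fit behave on known graphs", {
  tri <- make_clique(c("x", "y", "z"))
  expect_equal(average_degree(tri), 2)
  g <- igraph::sample_gnm(200, 400)
  igraph::V(g)$name <- paste0("n", 1:200)
  expect_equal(average_degree(g), mean(igraph::degree(g)))
  expect_error(average_degree(igraph::make_empty_graph(0)), "empty")
  # exact power law f(k) = 1000 k^-2: slope -2, correlation -1
  k <- 1:20
  fit <- lincnet:::powerlaw_fit_points(k, 1000 * k^-2)
  expect_equal(fit$exponent, 2, tolerance = 1e-10)
  expect_equal(fit$correlation, -1, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # preferential attachment yields a strong log-log trend
  set.seed(11)
  pa <- igraph::sample_pa(800, m = 2, directed = FALSE)
  igraph::V(pa)$name <- paste0("n", 1:800)
  pfit <- degree_powerlaw_fit(pa)
  expect_lt(pfit$correlation, -0.8)
  expect_gt(pfit$r_squared, 0.64)
  ring <- igraph::make_ring(10)
  igraph::V(ring)$name <- paste0("r", 1:10)
  expect_error(degree_powerlaw_fit(ring), "fewer than 3 distinct")
})
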