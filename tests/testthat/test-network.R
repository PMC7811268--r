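profiles_from_matrix <- function(m) {
  out <- tibble::as_tibble(m, rownames = "gene")
  out$complete <- TRUE
  out
}

test_that("pearson r matches the brute-force two-pass formula to 1e-12", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(1, 2, 2, 4, 5, 7)
  expect_equal(stats::cor(x, y), pearson_oracle(x, y), tolerance = 1e-12)
  expect_equal(stats::cor(x, x), 1, tolerance = 1e-12)
  expect_equal(stats::cor(x, -2 * x + 5), -1, tolerance = 1e-12)
  set.seed(77)
  for (i in 1:50) {
    a <- rnorm(6)
    b <- rnorm(6)
    expect_equal(stats::cor(a, b), pearson_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("pearson p has the stated t-tail form and behaviour", {
  expect_equal(pearson_p(0, 10), 1)
  p <- pearson_p(0.9, 6)
  expect_gt(p, 0.01)
  expect_lt(p, 0.02)
  # strictly decreasing in |r| for fixed n
  rs <- seq(0.05, 0.95, by = 0.05)
  ps <- pearson_p(rs, 6)
  expect_true(all(diff(ps) < 0))
  expect_equal(pearson_p(rs, 6), pearson_p(-rs, 6))
  expect_equal(pearson_p(1, 5), 0)
  # agrees with cor.test
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(6)
    b <- rnorm(6)
    expect_equal(pearson_p(stats::cor(a, b), 6),
                 stats::cor.test(a, b)$p.value, tolerance = 1e-12)
  }
})

test_that("planted identical profiles yield an edge with r = 1", {
  tf <- matrix(c(1, 2, 0, 4, 3, 5), 1, dimnames = list("TF1", profile_grid()))
  g <- matrix(c(1, 2, 0, 4, 3, 5), 1, dimnames = list("G1", profile_grid()))
  net <- build_network(tf, g)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$r, 1)
  expect_equal(net$edges$p_value, 0)
})

test_that("a decoy orthogonalised against all TFs gets no edge", {
  set.seed(42)
  tf_m <- matrix(rnorm(3 * 6), 3, dimnames = list(paste0("TF", 1:3),
                                                  profile_grid()))
  y <- rnorm(6)
  # residualise y against the TF profiles (and the intercept): every
  # correlation with a TF row is then exactly zero
  X <- cbind(1, t(tf_m))
  resid <- y - X %*% solve(crossprod(X), crossprod(X, y))
  g_m <- matrix(as.numeric(resid), 1, dimnames = list("G1", profile_grid()))
  rs <- as.numeric(stats::cor(t(tf_m), t(g_m)))
  expect_true(all(abs(rs) < 1e-10))
  net <- build_network(tf_m, g_m)
  expect_equal(nrow(net$edges), 0)
})

test_that("thresholds are monotone: tightening never adds edges", {
  sim <- simulate_expression(seed = 21)
  n1 <- build_network(sim$tf_profiles, sim$gene_profiles,
                      r_min = 0.8, p_max = 0.1)
  n2 <- build_network(sim$tf_profiles, sim$gene_profiles,
                      r_min = 0.9, p_max = 0.1)
  n3 <- build_network(sim$tf_profiles, sim$gene_profiles,
                      r_min = 0.8, p_max = 0.01)
  key <- function(net) paste(net$edges$tf, net$edges$gene)
  expect_true(all(key(n2) %in% key(n1)))
  expect_true(all(key(n3) %in% key(n1)))
  # strict boundary is a subset of inclusive at the same r_min
  ni <- build_network(sim$tf_profiles, sim$gene_profiles,
                      boundary = "inclusive")
  ns <- build_network(sim$tf_profiles, sim$gene_profiles,
                      boundary = "strict")
  expect_true(all(key(ns) %in% key(ni)))
})

test_that("relabelling nodes permutes edges identically", {
  sim <- simulate_expression(seed = 31)
  net <- build_network(sim$tf_profiles, sim$gene_profiles)
  relabel <- function(p, prefix) {
    p$gene <- paste0(prefix, p$gene)
    p
  }
  net2 <- build_network(relabel(sim$tf_profiles, "x_"),
                        relabel(sim$gene_profiles, "x_"))
  expect_equal(paste0("x_", net$edges$tf), net2$edges$tf)
  expect_equal(paste0("x_", net$edges$gene), net2$edges$gene)
  expect_equal(net$edges$r, net2$edges$r)
})

test_that("the bipartite contract and grid agreement are enforced", {
  sim <- simulate_expression(seed = 1)
  dup <- sim$gene_profiles
  dup$gene[1] <- sim$tf_profiles$gene[1]
  expect_error(build_network(sim$tf_profiles, dup),
               class = "lipidnet_input_error")
  short <- sim$gene_profiles |> dplyr::select(-"HT_168")
  expect_error(build_network(sim$tf_profiles, short),
               class = "lipidnet_grid_mismatch")
  expect_error(build_network(sim$tf_profiles[0, ], sim$gene_profiles),
               class = "lipidnet_empty_input")
  const <- sim$gene_profiles
  const[1, profile_grid()] <- as.list(rep(2, 6))
  expect_warning(build_network(sim$tf_profiles, const), "Constant")
})

test_that("hub summaries count edges per TF", {
  tf_m <- matrix(rep(c(1, 2, 0, 4, 3, 5), 2), 2, byrow = TRUE,
                 dimnames = list(c("TFa", "TFb"), profile_grid()))
  tf_m[2, ] <- c(5, 1, 4, 0, 2, 3)
  g_m <- rbind(tf_m[1, ], tf_m[1, ], tf_m[2, ])
  rownames(g_m) <- paste0("G", 1:3)
  net <- build_network(tf_m, g_m)
  hs <- hub_summary(net)
  expect_equal(hs$tf, c("TFa", "TFb"))
  expect_equal(hs$degree, c(2L, 1L))
  gl <- glance(net)
  expect_equal(gl$n_hub_tfs, 2L)
  expect_equal(gl$n_target_genes, 3L)
  expect_equal(gl$max_degree, 2L)
  # degenerate threshold: empty network, valid summaries
  empty <- build_network(tf_m, g_m, r_min = 1.01)
  expect_equal(nrow(empty$edges), 0)
  expect_equal(nrow(hub_summary(empty)), 0)
  expect_equal(glance(empty)$max_degree, 0L)
})

test_that("presets encode the two printed edge criteria", {
  rt <- network_preset("results_text")
  expect_equal(rt[c("r_min", "p_max", "boundary")],
               list(r_min = 0.9, p_max = 0.05, boundary = "strict"))
  fc <- network_preset("figure_caption")
  expect_equal(fc[c("r_min", "p_max", "boundary")],
               list(r_min = 0.9, p_max = 0.005, boundary = "inclusive"))
  expect_equal(rt$sign, "positive")
})

test_that("exports produce Cytoscape-loadable SIF, GraphML and TSV", {
  dir <- withr::local_tempdir()
  sim <- simulate_expression(seed = 12)
  net <- build_network(sim$tf_profiles, sim$gene_profiles)
  expect_gt(nrow(net$edges), 0)
  sif <- file.path(dir, "net.sif")
  write_network_sif(net, sif)
  lines <- readLines(sif)
  expect_equal(length(lines), nrow(net$edges))
  expect_true(all(grepl("^\\S+\tcoexpressed_with\t\\S+$", lines)))
  gml <- file.path(dir, "net.graphml")
  write_network_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_true("r" %in% igraph::edge_attr_names(g))
  tsv <- file.path(dir, "net.tsv")
  write_network_edges(net, tsv)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(net$edges))
  expect_equal(back$r, net$edges$r)
  # tidy() returns the same edges
  expect_equal(tidy(net), net$edges)
})

test_that("autoplot returns a ggplot for full and empty networks", {
  sim <- simulate_expression(seed = 12)
  net <- build_network(sim$tf_profiles, sim$gene_profiles)
  expect_s3_class(autoplot(net), "ggplot")
  empty <- build_network(sim$tf_profiles, sim$gene_profiles, r_min = 1.01)
  expect_s3_class(autoplot(empty), "ggplot")
})
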