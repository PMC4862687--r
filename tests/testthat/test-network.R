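test_that("graphs from proteins link identical pairs only", {
  set.seed(2)
  aa20 <- rownames(gpcrmine:::blosum62_matrix())[1:20]
  p1 <- paste(sample(aa20, 150, replace = TRUE), collapse = "")
  p2 <- paste(sample(aa20, 150, replace = TRUE), collapse = "")
  prots <- c(a1 = p1, a2 = p1, b1 = p2, b2 = p2)
  g <- build_graph(prots, p_threshold = 1e-9)
  expect_equal(nrow(g$edges), 2L)
  got <- paste(g$edges$node_i, g$edges$node_j)
  expect_setequal(got, c("a1 a2", "b1 b2"))
  expect_true(all(g$edges$attraction > 0))
})

test_that("edge sets are monotone in the threshold", {
  sim <- make_similarity_blocks(c(5, 4), between_p_law = c(1e-12, 1),
                                seed = 4)
  g9 <- build_graph(sim$edges, 1e-9)
  g6 <- build_graph(sim$edges, 1e-6)
  key <- function(g) paste(g$edges$node_i, g$edges$node_j)
  expect_true(all(key(g9) %in% key(g6)))
  expect_warning(
    g1 <- build_graph(data.frame(node_i = "a", node_j = "a", p_value = 1e-20),
                      nodes = "a"),
    "no edge")
  expect_equal(nrow(g1$edges), 0L)
})

test_that("layouts are deterministic and pull connected nodes together", {
  e <- data.frame(node_i = "a", node_j = "b", p_value = 1e-15)
  g <- build_graph(e, 1e-9)
  l1 <- force_layout(g, dims = 2, iterations = 600, seed = 3)
  l2 <- force_layout(g, dims = 2, iterations = 600, seed = 3)
  expect_identical(l1$coordinates, l2$coordinates)
  # two nodes, one edge: distance non-increasing after early steps
  dists <- vapply(c(100, 200, 400, 600), function(it) {
    X <- force_layout(g, dims = 2, iterations = it, seed = 3)$coordinates
    sqrt(sum((X[1, ] - X[2, ])^2))
  }, numeric(1))
  expect_true(all(diff(dists) <= 1e-8))
})

test_that("planted blocks separate in space and energy relaxes", {
  sim <- make_similarity_blocks(c(10, 10), seed = 6)
  g <- build_graph(sim$edges, 1e-9)
  lay <- force_layout(g, dims = 3, iterations = 20000, seed = 8)
  X <- lay$coordinates
  blocks <- split(sim$truth$node, sim$truth$block)
  d <- as.matrix(stats::dist(X))
  within <- c(d[blocks[[1]], blocks[[1]]][upper.tri(diag(10))],
              d[blocks[[2]], blocks[[2]]][upper.tri(diag(10))])
  between <- d[blocks[[1]], blocks[[2]]]
  expect_lt(mean(within), mean(between))
  # energy over the second half of the schedule is non-increasing
  e_mid <- layout_energy(g, force_layout(g, 3, 10000, 8))
  e_end <- layout_energy(g, lay)
  expect_lte(e_end, e_mid + 1e-8)
})

test_that("convex clusters recover planted families and respect min size", {
  sim <- make_similarity_blocks(c(6, 5, 4), seed = 3)
  g <- build_graph(sim$edges, 1e-9)
  lay <- force_layout(g, dims = 3, iterations = 2000, seed = 5)
  cs <- extract_clusters(g, lay)
  expect_equal(lengths(cs$clusters, use.names = FALSE), c(6L, 5L, 4L))
  pred <- rep(seq_along(cs$clusters), lengths(cs$clusters))
  truth <- sim$truth$block[match(unlist(cs$clusters), sim$truth$node)]
  expect_equal(mclust::adjustedRandIndex(pred, truth), 1.0)
  expect_length(cs$unclustered, 0L)
  expect_true(all(cs$convexity >= 0 & cs$convexity <= 1))

  # a lone block of three never reaches the four-gene minimum
  sim3 <- make_similarity_blocks(3L, seed = 2)
  g3 <- build_graph(sim3$edges, 1e-9)
  cs3 <- extract_clusters(g3, force_layout(g3, 2, 200, 1))
  expect_length(cs3$clusters, 0L)
  expect_setequal(cs3$unclustered, sim3$truth$node)
})

test_that("cluster sets always partition the node set", {
  for (s in 1:8) {
    sizes <- sample(2:8, sample(2:4, 1), replace = TRUE)
    sim <- make_similarity_blocks(sizes, seed = s)
    g <- build_graph(sim$edges, 1e-9)
    cs <- extract_clusters(g, NULL)
    all_ids <- c(unlist(cs$clusters), cs$unclustered)
    expect_setequal(all_ids, g$nodes)
    expect_equal(length(all_ids), length(g$nodes))  # disjoint cover
  }
})

test_that("uniform sparse graphs rarely produce clusters", {
  # 4 random edges on 20 nodes: a four-member component needs at least
  # three of them to coincide on four nodes, which is rare
  n_clustered <- 0L
  for (s in 1:100) {
    nodes <- sprintf("n%02d", 1:20)
    pairs <- t(utils::combn(nodes, 2))
    set.seed(s)
    keep <- sample(nrow(pairs), 4)
    edges <- data.frame(node_i = pairs[keep, 1], node_j = pairs[keep, 2],
                        p_value = 10^stats::runif(4, -20, -10))
    g <- build_graph(edges, 1e-9, nodes = nodes)
    cs <- extract_clusters(g, NULL)
    if (length(cs$clusters)) n_clustered <- n_clustered + 1L
  }
  expect_lt(n_clustered / 100, 0.3)
})

test_that("cross-species co-clustering inherits and withholds labels", {
  sim <- make_similarity_blocks(c(5, 4, 4), seed = 9)
  # block 1: planarian with human NPY references; block 2: planarian only;
  # block 3: tie between two reference families
  nodes <- sim$truth$node
  b <- split(nodes, sim$truth$block)
  ref <- c(stats::setNames(rep("NPY", 2), b[[1]][1:2]),
           stats::setNames(c("NPY", "amine"), b[[3]][1:2]))
  g <- build_graph(sim$edges, 1e-6)
  lab <- co_cluster_label(g, ref)
  expect_true(all(lab$family[lab$node %in% b[[1]][3:5]] == "NPY"))
  expect_true(all(lab$family[lab$node %in% b[[2]]] == "phylum-specific"))
  amb <- lab[lab$node %in% b[[3]][3:4], ]
  expect_true(all(amb$family == "ambiguous"))
  expect_true(all(amb$tied_families == "NPY,amine" |
                    amb$tied_families == "amine,NPY"))
})

test_that("curation directives merge and split clusters with a log", {
  sim <- make_similarity_blocks(c(6, 5, 4), seed = 3)
  g <- build_graph(sim$edges, 1e-9)
  cs <- extract_clusters(g, NULL)
  cur <- apply_curation(cs, data.frame(
    action = c("merge", "split"), target = c("C01", "C03"),
    other = c("C02", NA), stringsAsFactors = FALSE))
  expect_length(cur$clusters, 1L)
  expect_length(cur$clusters$C01, 11L)
  expect_length(cur$unclustered, 4L)
  expect_length(cur$curation_log, 2L)
  expect_error(apply_curation(cs, data.frame(action = "merge", target = "C01",
                                             other = "C99")), "unknown")
})
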