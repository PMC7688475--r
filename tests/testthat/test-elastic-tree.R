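test_that("energy components satisfy the analytic cases", {
  # data exactly on the nodes: MSD = 0
  G <- path_graph(3)
  X <- G$nodes
  en <- graph_energy(G, X)
  expect_equal(en$MSD, 0)

  # harmonic star: center at the mean of its leaves gives U_R = 0
  Y <- y_graph(1)
  expect_equal(colMeans(Y$nodes[2:4, ]), c(0, 0), tolerance = 1e-12)
  enY <- graph_energy(Y, Y$nodes)
  expect_equal(enY$U_R, 0, tolerance = 1e-12)

  # single edge of length d, degrees <= 2: U_E = lambda * d^2 exactly
  d <- 1.7
  G2 <- principal_graph(rbind(c(0, 0), c(d, 0)), matrix(c(1L, 2L), 1),
                        elastic_params(lambda = 0.05, alpha = 0.01))
  en2 <- graph_energy(G2, rbind(c(0, 0), c(d, 0)))
  expect_equal(en2$U_E, 0.05 * d^2, tolerance = 1e-12)

  # branching penalty: each edge of a 3-star carries lambda + alpha * (3 - 2)
  enY2 <- graph_energy(y_graph(1), y_graph(1)$nodes)
  expect_equal(enY2$U_E, 3 * (0.05 + 0.01) * 1^2, tolerance = 1e-12)

  expect_error(graph_energy(principal_graph(matrix(0, 0, 2),
                                            matrix(integer(0), 0, 2)),
                            matrix(0, 1, 2)), "empty graph")
})

test_that("point partition matches brute force and breaks ties low", {
  G <- path_graph(5)
  # a point equal to a node position maps to that node
  expect_equal(partition_points(G$nodes[3, , drop = FALSE], G)$assignment, 3L)
  # equidistant between nodes 1 and 2 goes to node 1
  expect_equal(partition_points(rbind(c(0.5, 0)), G)$assignment, 1L)
  set.seed(8)
  X <- matrix(rnorm(200), 100, 2) * 2
  p <- partition_points(X, G)
  brute <- apply(X, 1, function(x)
    which.min(colSums((t(G$nodes) - x)^2)))
  expect_equal(p$assignment, unname(brute))
  # trimming flags points beyond R0
  Gt <- principal_graph(G$nodes, G$edges, elastic_params(R0 = 1))
  pt <- partition_points(rbind(c(0, 5), c(0, 0.5)), Gt)
  expect_equal(pt$trimmed, c(TRUE, FALSE))
})

test_that("node-position optimisation is monotone and hits analytic optima", {
  # exactly symmetric line data: converged 2-node solution symmetric about
  # the origin
  set.seed(2)
  t <- runif(100, 0.02, 1)
  half <- cbind(t, rnorm(100, sd = 0.01))
  X <- rbind(half, -half)
  G <- principal_graph(rbind(c(-0.2, 0.3), c(0.1, -0.2)),
                       matrix(c(1L, 2L), 1))
  fit <- fit_node_positions(G, X)
  expect_true(all(diff(fit$trace) <= 1e-12))
  expect_equal(fit$graph$nodes[1, ], -fit$graph$nodes[2, ], tolerance = 0.05)

  # single node: optimum is the data mean (k-means with k = 1)
  G1 <- principal_graph(matrix(c(5, 5), 1), matrix(integer(0), 0, 2))
  f1 <- fit_node_positions(G1, X)
  expect_equal(f1$graph$nodes[1, ], colMeans(X), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("grammar growth recovers a path on line data", {
  set.seed(10)
  t <- runif(300)
  X <- cbind(t, 0.02 * rnorm(300), 0.02 * rnorm(300))
  fit <- grow_tree(X, n_nodes = 10, seed = 10)
  dg <- graph_degrees(fit$graph)
  expect_equal(sum(dg == 1), 2L)       # a path: exactly two leaves
  expect_equal(sum(dg > 2), 0L)
  expect_true(all(diff(fit$report$trace$U) <= 1e-9))
})

test_that("grammar growth recovers a 3-armed star", {
  gen <- generate_branching_dataset(
    tree_spec_star(3, arm_lengths = 1, m = 4, sigma = 0.05,
                   n_per_branch = 100), seed = 6)
  fit <- grow_tree(gen$X, n_nodes = 20, seed = 6)
  dg <- graph_degrees(fit$graph)
  expect_equal(sum(dg == 1), 3L)
  expect_equal(sum(dg == 3), 1L)
  # each accepted candidate is the energy minimiser of its step
  for (st in fit$report$candidate_energies)
    expect_equal(st$accepted, which.min(st$energies))
})

test_that("raising the complexity penalty never adds branching nodes", {
  gen <- generate_branching_dataset(
    tree_spec_star(3, arm_lengths = 1, m = 4, sigma = 0.08,
                   n_per_branch = 80), seed = 14)
  n_branching <- vapply(c(0.001, 0.01, 0.1), function(a) {
    fit <- grow_tree(gen$X, n_nodes = 15, seed = 14,
                     params = elastic_params(alpha = a))
    sum(graph_degrees(fit$graph) > 2)
  }, numeric(1))
  expect_true(all(diff(n_branching) <= 0))
})

test_that("pruning removes single-edge terminal segments only", {
  # a path is untouched
  P <- path_graph(4)
  expect_equal(prune_tree(P)$edges, P$edges)
  # Y-tree with arm lengths 1, 3, 3 (in edges): the 1-edge arm goes
  nodes <- rbind(c(0, 0), c(0, 1),
                 c(1, 0), c(2, 0), c(3, 0),
                 c(-1, 0), c(-2, 0), c(-3, 0))
  edges <- rbind(c(1, 2), c(1, 3), c(3, 4), c(4, 5), c(1, 6), c(6, 7), c(7, 8))
  G <- principal_graph(nodes, edges)
  pruned <- prune_tree(G)
  expect_equal(nrow(pruned$nodes), 7L)
  dg <- graph_degrees(pruned)
  expect_equal(sum(dg == 1), 2L)       # now a path
  # degenerate: a bare 3-star collapses to its center with a warning
  expect_warning(collapsed <- prune_tree(y_graph(1)), "collapsed")
  expect_equal(nrow(collapsed$nodes), 1L)
})

test_that("leaf extension makes extreme points project inside edges", {
  # unit segment with a point beyond the leaf
  G <- principal_graph(rbind(c(0, 0), c(1, 0)), matrix(c(1L, 2L), 1))
  X <- rbind(c(0.2, 0), c(0.8, 0), c(1.5, 0))
  ext <- extend_leaves(G, X)
  expect_equal(ext$nodes[2, ], c(1.5, 0))
  # points already projecting strictly inside leave the graph unchanged
  X2 <- rbind(c(0.3, 0.1), c(0.6, -0.1))
  expect_equal(extend_leaves(G, X2)$nodes, G$nodes)
  # seeded line data: extension removes the pile-up of points on leaf nodes
  # (only the extremal point defining each leaf may still sit exactly on it)
  set.seed(15)
  Xl <- cbind(runif(200, -2, 2), rnorm(200, sd = 0.05))
  fit <- grow_tree(Xl, n_nodes = 8, seed = 15)
  on_leaf <- function(G) {
    proj <- project_points(Xl, G)
    dg <- graph_degrees(G)
    sum(vapply(seq_len(200), function(i) {
      e <- proj$edge[i]; ep <- proj$eps[i]
      (ep <= 0 && dg[G$edges[e, 1]] == 1) ||
        (ep >= 1 && dg[G$edges[e, 2]] == 1)
    }, logical(1)))
  }
  Ge <- extend_leaves(fit$graph, Xl)
  expect_gt(on_leaf(fit$graph), 2L)
  expect_lte(on_leaf(Ge), 2L)
})

test_that("projection matches the per-edge closed form", {
  G <- path_graph(3)
  # midpoint of an edge
  pr <- project_point(c(0.5, 1), G)
  expect_equal(pr$eps, 0.5)
  expect_equal(pr$edge, 1L)
  expect_equal(pr$residual2, 1)
  # a node position projects with zero residual at an edge end
  pr2 <- project_point(G$nodes[2, ], G)
  expect_equal(pr2$residual2, 0)
  expect_true(pr2$eps %in% c(0, 1))
  # brute force over a 10-edge random tree
  set.seed(22)
  fitg <- grow_tree(matrix(rnorm(400), 200, 2), n_nodes = 11, seed = 22)$graph
  X <- matrix(rnorm(100), 50, 2)
  pr3 <- project_points(X, fitg)
  for (i in 1:50) {
    d2 <- vapply(seq_len(nrow(fitg$edges)), function(e) {
      a <- fitg$nodes[fitg$edges[e, 1], ]; b <- fitg$nodes[fitg$edges[e, 2], ]
      v <- b - a
      tt <- min(1, max(0, sum((X[i, ] - a) * v) / sum(v^2)))
      sum((X[i, ] - a - tt * v)^2)
    }, numeric(1))
    expect_equal(pr3$residual2[i], min(d2), tolerance = 1e-12)
    expect_equal(pr3$edge[i], which.min(d2))
  }
})

test_that("explained variance is exact in the degenerate cases", {
  G <- path_graph(3)
  X <- rbind(c(0.3, 0), c(1.2, 0), c(1.9, 0))
  expect_equal(explained_variance(G, X), 1.0)
  X2 <- matrix(rnorm(40), 20, 2)
  G1 <- principal_graph(matrix(colMeans(X2), 1), matrix(integer(0), 0, 2))
  expect_equal(explained_variance(G1, X2), 0, tolerance = 1e-12)
  expect_error(explained_variance(G, matrix(1, 3, 2)), "zero total variance")
  # low-noise line data: explained variance close to 1
  set.seed(23)
  sg <- 0.03
  Xl <- cbind(runif(300, 0, 2), rnorm(300, sd = sg))
  fit <- grow_tree(Xl, n_nodes = 12, seed = 23)
  expect_gte(explained_variance(extend_leaves(fit$graph, Xl), Xl),
             1 - 10 * sg^2)
})

test_that("graph JSON serialization round-trips", {
  G <- y_graph(2)
  path <- tempfile(fileext = ".json")
  write_principal_graph(G, path, provenance = list(seed = 1))
  G2 <- read_principal_graph(path)
  expect_equal(G2$nodes, G$nodes, ignore_attr = TRUE)
  expect_equal(G2$edges, G$edges, ignore_attr = TRUE)
  expect_equal(G2$params$lambda, G$params$lambda)
  expect_equal(attr(G2, "provenance")$seed, 1)
})
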