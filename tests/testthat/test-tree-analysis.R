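test_that("segment decomposition handles the canonical cases", {
  # path A-B-C: one segment
  segs <- decompose_segments(rbind(c(1, 2), c(2, 3)), n_nodes = 3)
  expect_length(segs, 1L)
  expect_equal(segs[[1]]$kind, "terminal")
  # Y graph: three terminal segments
  segsY <- decompose_segments(y_graph(1))
  expect_length(segsY, 3L)
  expect_true(all(vapply(segsY, `[[`, character(1), "kind") == "terminal"))
  # H tree: 4 terminal + 1 internal
  segsH <- decompose_segments(
    rbind(c(1, 2), c(1, 3), c(1, 4), c(4, 5), c(4, 6)), n_nodes = 6)
  expect_equal(sort(vapply(segsH, `[[`, character(1), "kind")),
               c("internal", rep("terminal", 4)))
  # disjoint triangle + isolated node
  segsC <- decompose_segments(rbind(c(1, 2), c(2, 3), c(3, 1)), n_nodes = 4)
  expect_length(segsC, 2L)
  expect_setequal(vapply(segsC, `[[`, character(1), "kind"),
                  c("cycle", "isolated"))
})

test_that("segment decomposition partitions edges exactly once on all small
           trees and cycles (brute-force closure oracle)", {
  check_graph <- function(edges, n) {
    segs <- decompose_segments(edges, n_nodes = n)
    keys <- lapply(segs, function(s) segment_edge_key(s$path, edges))
    keys <- keys[lengths(keys) > 0]
    # edge-partition property: every edge in exactly one segment
    expect_equal(sort(unlist(keys)), seq_len(nrow(edges)))
    # equality with the independent closure oracle
    oracle <- oracle_segments(edges, n)
    expect_setequal(lapply(keys, paste, collapse = "-"),
                    lapply(oracle, paste, collapse = "-"))
  }
  for (n in 2:6) for (edges in pruefer_trees(n)) check_graph(edges, n)
  for (n in 3:6) {  # cycles
    check_graph(cbind(seq_len(n), c(seq_len(n)[-1], 1L)), n)
  }
  # a lollipop (cycle + tail) and a graph with an isolated node
  check_graph(rbind(c(1, 2), c(2, 3), c(3, 1), c(3, 4), c(4, 5)), 5)
  check_graph(rbind(c(1, 2), c(2, 3)), 4)
})

test_that("segment partition uses the second-nearest-node rule at branchings", {
  G <- y_graph(2)           # center 1; arms (2,3), (4,5), (6,7)
  segs <- decompose_segments(G)
  # observation nearest a degree-2 node gets that node's unique segment
  x_arm1 <- G$nodes[2, , drop = FALSE] + 0.01
  lab <- partition_by_segments(x_arm1, G, segs)
  seg_arm1 <- which(vapply(segs, function(s) 2 %in% s$path, logical(1)))
  expect_equal(as.integer(lab), seg_arm1)
  # observation nearest the branching center but leaning toward arm 2
  x_center <- matrix(0.22 * G$nodes[4, ], 1)
  lab2 <- partition_by_segments(x_center, G, segs)
  seg_arm2 <- which(vapply(segs, function(s) 4 %in% s$path, logical(1)))
  expect_equal(as.integer(lab2), seg_arm2)
})

test_that("segment labels agree with nearest-edge assignment on dense trees", {
  gen <- generate_branching_dataset(
    tree_spec_star(3, arm_lengths = 1, m = 4, sigma = 0.05,
                   n_per_branch = 70), seed = 19)
  fit <- grow_tree(gen$X, n_nodes = 30, seed = 19)
  G <- fit$graph
  segs <- decompose_segments(G)
  labels <- partition_by_segments(gen$X, G, segs)
  # alternative rule: nearest edge decides the segment
  proj <- project_points(gen$X, G)
  edge_seg <- vapply(seq_len(nrow(G$edges)), function(e) {
    hit <- which(vapply(segs, function(s)
      length(segment_edge_key(s$path, G$edges)) > 0 &&
        e %in% segment_edge_key(s$path, G$edges), logical(1)))
    hit[1]
  }, integer(1))
  by_edge <- edge_seg[proj$edge]
  expect_gte(mean(by_edge == labels), 0.95)
})

test_that("root selection recovers a planted enrichment and flags the null", {
  G <- path_graph(5, m = 2)
  set.seed(30)
  X <- G$nodes[rep(1:5, each = 40), ] + matrix(rnorm(400, sd = 0.1), 200)
  labels <- rep("other", 200)
  labels[partition_points(X, G)$assignment == 4] <- "mild"
  sel <- select_root(G, X, labels, "mild")
  expect_true(sel$significant)
  expect_equal(sel$node, 4L)
  # uniform class: flagged, no node returned
  labs_u <- rep(c("mild", "other"), 100)
  sel_u <- select_root(G, X, labs_u, "mild")
  expect_false(sel_u$significant)
  expect_true(is.na(sel_u$node))
  expect_error(select_root(G, X, labels, "absent"), "absent")
})

test_that("trajectories enumerate root-to-leaf paths", {
  P <- path_graph(3)
  tr <- extract_trajectories(P, root = 2)
  expect_length(tr, 2L)
  Y <- y_graph(2)
  trY <- extract_trajectories(Y, root = 3)   # root at a leaf
  expect_length(trY, 2L)
  expect_true(all(vapply(trY, function(t) t$path[1] == 3, logical(1))))
  # 10-leaf star with internal root
  edges <- cbind(1L, 2:11)
  S <- principal_graph(cbind(c(0, cos(1:10)), c(0, sin(1:10))), edges)
  expect_length(extract_trajectories(S, root = 1), 10L)
  expect_error(extract_trajectories(P, root = 9), "root")
})

test_that("pseudo-time follows the geodesic edge-count rule", {
  P <- path_graph(5)          # nodes at x = 0..4, root = node 1
  # projection on the root-incident edge at eps = 0.3
  pt <- compute_pseudotime(rbind(c(0.3, 0.5)), P, root = 1)
  expect_equal(pt$pseudotime, 0.3)
  # d0 = 2, d1 = 3, eps = 0.25 -> Pt = 2.25
  pt2 <- compute_pseudotime(rbind(c(2.25, 0.4)), P, root = 1)
  expect_equal(pt2$pseudotime, 2.25)
  expect_equal(pt2$edge, 3L)
  # root at the other end: same projection now has d0 = 2 > d1, Pt = d0 - eps
  pt3 <- compute_pseudotime(rbind(c(2.25, 0.4)), P, root = 5)
  expect_equal(pt3$pseudotime, 2 - 0.25)   # d0 = |5->3| = 2 > d1, Pt = d0 - eps
  # euclidean units reproduce arc length for unit edges
  pt4 <- compute_pseudotime(rbind(c(2.25, 0.4)), P, root = 1,
                            units = "euclidean")
  expect_equal(pt4$pseudotime, 2.25)
})

test_that("pseudo-time is continuous along a trajectory and lists the
           trajectories owning each projection edge", {
  Y <- y_graph(3)
  trY <- extract_trajectories(Y, root = 4)    # root = leaf of arm 1
  X <- rbind(0.55 * Y$nodes[2, ],             # on the shared arm
             0.55 * Y$nodes[8, ])             # on arm 3 only
  pt <- compute_pseudotime(X, Y, root = 4)
  shared <- pt$trajectories[[1]]
  expect_length(shared, 2L)                   # both trajectories pass here
  expect_length(pt$trajectories[[2]], 1L)
  # continuity: walking along one trajectory, Pt of points sliding along
  # consecutive edges changes by less than one edge unit
  tpath <- seq(0.01, 2.99, by = 0.05)
  dirs <- rbind(Y$nodes[4, ] / 3)
  Xw <- t(vapply(tpath, function(s) {
    if (s <= 1) (1 - s) * Y$nodes[4, ] + s * Y$nodes[3, ]
    else if (s <= 2) (2 - s) * Y$nodes[3, ] + (s - 1) * Y$nodes[2, ]
    else (3 - s) * Y$nodes[2, ] + (s - 2) * Y$nodes[1, ]
  }, numeric(2)))
  ptw <- compute_pseudotime(Xw, Y, root = 4)
  expect_true(all(abs(diff(ptw$pseudotime)) < 1))
  expect_true(all(diff(ptw$pseudotime) > 0))  # monotone along the walk
})
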