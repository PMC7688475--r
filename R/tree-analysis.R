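#' Decompose a graph into non-branching segments
#'
#' A segment is a maximal path whose interior nodes all have degree 2:
#' internal segments connect two branching nodes (degree > 2), terminal
#' segments end in a leaf.  The decomposition partitions the edge set
#' uniquely.  It is computed by a depth-first walk that records visited
#' edges (not only nodes), which also handles the exceptional cases: an
#' isolated cycle is one `"cycle"` segment and an isolated node is one
#' `"isolated"` singleton segment.
#'
#' @param G A [principal_graph()], or a bare edge list (2-column matrix)
#'   together with `n_nodes`.
#' @param n_nodes Number of nodes when `G` is a bare edge list.
#' @return A list of class `segment_list`; each element has `id`, `path`
#'   (ordered node indices), and `kind` (`"internal"`, `"terminal"`,
#'   `"cycle"` or `"isolated"`).
#' @export
decompose_segments <- function(G, n_nodes = NULL) {
  if (inherits(G, "principal_graph")) {
    edges <- G$edges; n <- nrow(G$nodes)
  } else {
    edges <- as.matrix(G)
    if (length(edges) == 0) edges <- matrix(integer(0), 0, 2)
    n <- n_nodes %||% max(c(edges, 0L))
  }
  deg <- tabulate(as.vector(edges), n)
  # incidence: edges at each node
  inc <- lapply(seq_len(n), function(v)
    which(edges[, 1] == v | edges[, 2] == v))
  other_end <- function(e, v) if (edges[e, 1] == v) edges[e, 2] else edges[e, 1]
  visited <- logical(nrow(edges))
  segments <- list()
  add_segment <- function(path, kind) {
    segments[[length(segments) + 1L]] <<-
      list(id = length(segments) + 1L, path = path, kind = kind)
  }
  walk <- function(start, e0) {
    path <- start
    v <- start; e <- e0
    repeat {
      visited[e] <<- TRUE
      v <- other_end(e, v)
      path <- c(path, v)
      if (deg[v] != 2L || v == start) break
      nxt <- inc[[v]][!visited[inc[[v]]]]
      if (!length(nxt)) break
      e <- nxt[1]
    }
    path
  }
  # start segments from every special (non degree-2) node
  for (v in which(deg > 0L & deg != 2L)) {
    for (e in inc[[v]]) {
      if (visited[e]) next
      path <- walk(v, e)
      ends <- deg[c(path[1], path[length(path)])]
      add_segment(path, if (any(ends <= 1L)) "terminal" else "internal")
    }
  }
  # remaining components are pure cycles (all degree 2)
  for (e in which(!visited)) {
    if (visited[e]) next
    v <- edges[e, 1]
    path <- walk(v, e)
    add_segment(path, "cycle")
  }
  for (v in which(deg == 0L)) add_segment(v, "isolated")
  structure(segments, class = "segment_list")
}

#' @export
print.segment_list <- function(x, ...) {
  kinds <- table(vapply(x, `[[`, character(1), "kind"))
  cat(sprintf("<segment_list> %d segments (%s)\n", length(x),
              paste(sprintf("%d %s", kinds, names(kinds)), collapse = ", ")))
  invisible(x)
}

# node -> segment ids membership
segment_membership <- function(segments, n_nodes) {
  mem <- vector("list", n_nodes)
  for (s in segments) {
    for (v in unique(s$path)) mem[[v]] <- c(mem[[v]], s$id)
  }
  mem
}

#' Partition observations by nearest non-branching segment
#'
#' Each observation is labelled with the segment containing its nearest
#' node.  When that node is a branching node (shared by several segments),
#' the label is the candidate segment containing the second-nearest node
#' among all nodes of the candidate segments.
#'
#' @param X Data matrix.
#' @param G A [principal_graph()].
#' @param segments Precomputed [decompose_segments()] result (optional).
#' @return Integer vector of segment ids, one per observation, with the
#'   `segment_list` attached as attribute `"segments"`.
#' @export
partition_by_segments <- function(X, G, segments = NULL) {
  X <- as.matrix(X)
  if (is.null(segments)) segments <- decompose_segments(G)
  d2 <- cross_dist2(X, G$nodes)
  nearest <- max.col(-d2, ties.method = "first")
  mem <- segment_membership(segments, nrow(G$nodes))
  labels <- integer(nrow(X))
  for (i in seq_len(nrow(X))) {
    cand <- mem[[nearest[i]]]
    if (length(cand) == 1L) { labels[i] <- cand; next }
    cand_nodes <- sort(unique(unlist(lapply(segments[cand], `[[`, "path"))))
    cand_nodes <- setdiff(cand_nodes, nearest[i])
    second <- cand_nodes[which.min(d2[i, cand_nodes])]
    hit <- cand[vapply(segments[cand], function(s) second %in% s$path,
                       logical(1))]
    labels[i] <- hit[1]
  }
  attr(labels, "segments") <- segments
  labels
}

#' Select a root node by class enrichment
#'
#' For every node, observations are split into members (nearest node is this
#' node) and non-members, and a 2x2 chi-squared statistic against
#' `label == target_class` is computed.  The root candidate is the node with
#' the largest statistic among nodes positively enriched for the target
#' class.  If no node reaches significance the result is flagged and the
#' user should supply a root explicitly; root selection is advisory and all
#' downstream functions take an explicit root.
#'
#' @param G A [principal_graph()].
#' @param X Data matrix.
#' @param labels Class label per observation.
#' @param target_class The class marking the start of progression (e.g. the
#'   least severe state).
#' @param alpha Significance level for the flag (default 0.05).
#' @return List with `node` (best candidate, `NA` if none enriched),
#'   `significant` (logical flag), and `stats` (per-node chi-squared,
#'   p-value, enrichment sign).
#' @export
select_root <- function(G, X, labels, target_class, alpha = 0.05) {
  X <- as.matrix(X)
  if (!any(labels == target_class, na.rm = TRUE))
    stopf("target class '%s' absent from labels", target_class)
  nearest <- partition_points(X, G)$assignment
  is_target <- labels == target_class
  n <- length(labels)
  stats_ <- data.frame(node = seq_len(nrow(G$nodes)), chi2 = 0,
                       p = 1, enriched = FALSE)
  for (j in seq_len(nrow(G$nodes))) {
    memb <- nearest == j
    tab <- table(factor(memb, c(FALSE, TRUE)),
                 factor(is_target, c(FALSE, TRUE)))
    if (sum(memb) == 0 || sum(memb) == n) next
    expected <- sum(memb) * sum(is_target, na.rm = TRUE) / n
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    stats_$chi2[j] <- unname(ct$statistic)
    stats_$p[j] <- ct$p.value
    stats_$enriched[j] <- tab["TRUE", "TRUE"] > expected
  }
  pos <- which(stats_$enriched & stats_$p < alpha)
  if (!length(pos)) {
    return(list(node = NA_integer_, significant = FALSE, stats = stats_))
  }
  list(node = pos[which.max(stats_$chi2[pos])], significant = TRUE,
       stats = stats_)
}

#' Enumerate root-to-leaf trajectories of a tree
#'
#' @param G A [principal_graph()] tree.
#' @param root Root node index.
#' @param segments Precomputed [decompose_segments()] (optional), used to
#'   record which segments each trajectory traverses.
#' @return List of class `trajectory_list`; each element has `id`, `path`
#'   (root first), `leaf`, and `segments` (ids of segments with at least one
#'   edge on the path).
#' @export
extract_trajectories <- function(G, root, segments = NULL) {
  stopifnot(graph_is_tree(G))
  if (!is_count(root) || root > nrow(G$nodes)) stopf("root not in graph")
  if (is.null(segments)) segments <- decompose_segments(G)
  g <- as_igraph(G)
  dg <- graph_degrees(G)
  leaves <- setdiff(which(dg <= 1L), root)
  paths <- igraph::shortest_paths(g, from = root, to = leaves)$vpath
  seg_edges <- lapply(segments, function(s)
    cbind(s$path[-length(s$path)], s$path[-1]))
  trajs <- vector("list", length(leaves))
  for (i in seq_along(leaves)) {
    p <- as.integer(paths[[i]])
    pe <- cbind(p[-length(p)], p[-1])
    on_path <- function(se) any(
      (se[, 1] %in% p) & (se[, 2] %in% p) &
        (abs(match(se[, 1], p) - match(se[, 2], p)) == 1))
    segs <- which(vapply(seg_edges, on_path, logical(1)))
    trajs[[i]] <- list(id = i, path = p, leaf = leaves[i], segments = segs)
  }
  structure(trajs, class = "trajectory_list", root = root)
}

#' @export
print.trajectory_list <- function(x, ...) {
  cat(sprintf("<trajectory_list> %d root-to-leaf trajectories (root node %d)\n",
              length(x), attr(x, "root")))
  invisible(x)
}

#' Pseudo-time of every observation relative to a root node
#'
#' Pseudo-time is the geodesic distance along the tree from the root to the
#' observation's projection.  With `{p, eps}` the projection of `x` onto
#' edge `p`, and `d0`, `d1` the graph distances from the root to the two
#' ends of that edge, `Pt = d0 + eps` when `d0 < d1` and `Pt = d0 - eps`
#' otherwise.  Distances are measured in edge units by default (each edge
#' counts 1); `units = "euclidean"` uses embedded edge lengths instead.
#'
#' @param X Data matrix.
#' @param G A [principal_graph()] tree.
#' @param root Root node index.
#' @param segments,trajectories Precomputed decompositions (optional).
#' @param units `"edges"` (default) or `"euclidean"`.
#' @return A data.frame of class `pseudotime_table` with columns `row_id`,
#'   `pseudotime`, `segment`, `edge`, `eps`, `residual2` and a list column
#'   `trajectories` (ids of all trajectories whose edge set contains the
#'   projection edge).
#' @export
compute_pseudotime <- function(X, G, root, segments = NULL,
                               trajectories = NULL,
                               units = c("edges", "euclidean")) {
  units <- match.arg(units)
  X <- as.matrix(X)
  stopifnot(graph_is_tree(G))
  if (is.null(segments)) segments <- decompose_segments(G)
  if (is.null(trajectories)) trajectories <- extract_trajectories(G, root, segments)
  proj <- project_points(X, G)
  g <- as_igraph(G)
  w <- if (units == "edges") rep(1, nrow(G$edges)) else {
    dl <- G$nodes[G$edges[, 1], , drop = FALSE] -
          G$nodes[G$edges[, 2], , drop = FALSE]
    sqrt(rowSums(dl^2))
  }
  nd <- as.vector(igraph::distances(g, v = root, weights = w))
  d0 <- nd[G$edges[proj$edge, 1]]
  d1 <- nd[G$edges[proj$edge, 2]]
  scale_ <- if (units == "edges") 1 else w[proj$edge]
  pt <- ifelse(d0 < d1, d0 + proj$eps * scale_, d0 - proj$eps * scale_)
  seg_labels <- partition_by_segments(X, G, segments)
  # map each edge to the trajectories whose paths contain it
  edge_traj <- vector("list", nrow(G$edges))
  for (tr in trajectories) {
    p <- tr$path
    steps <- cbind(p[-length(p)], p[-1])
    for (r in seq_len(nrow(steps))) {
      e <- which((G$edges[, 1] == steps[r, 1] & G$edges[, 2] == steps[r, 2]) |
                 (G$edges[, 1] == steps[r, 2] & G$edges[, 2] == steps[r, 1]))
      edge_traj[[e]] <- c(edge_traj[[e]], tr$id)
    }
  }
  out <- data.frame(row_id = rownames(X) %||% as.character(seq_len(nrow(X))),
                    pseudotime = pt, segment = as.integer(seg_labels),
                    edge = proj$edge, eps = proj$eps,
                    residual2 = proj$residual2)
  out$trajectories <- edge_traj[proj$edge]
  attr(out, "root") <- root
  attr(out, "units") <- units
  attr(out, "trajectory_list") <- trajectories
  attr(out, "segment_list") <- segments
  class(out) <- c("pseudotime_table", "data.frame")
  out
}
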