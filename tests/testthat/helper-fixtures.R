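# fixtures built in code; all randomness under explicit seeds

# small mixed table written to temp files, for the reader tests
write_toy_table <- function(lines, meta, dir = tempfile("fixture")) {
  if (!dir.exists(dir)) dir.create(dir)
  table_path <- file.path(dir, "table.csv")
  meta_path <- file.path(dir, "meta.json")
  writeLines(lines, table_path)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE)
  list(table = table_path, meta = meta_path)
}

toy_meta <- function() list(
  list(name = "severity", kind = "ordinal", levels = c("0", "1", "2"),
       role = "feature"),
  list(name = "age", kind = "continuous", role = "feature"))

# quantified matrix wrapper for matrices built directly in tests
qm_wrap <- function(M, maps = list(), provenance = NULL) {
  structure(list(values = M, provenance = provenance, maps = maps,
                 center = NULL, scale = NULL),
            class = "quantified_matrix")
}

# simple embedded path graph on the x-axis: nodes at 0..(n-1)
path_graph <- function(n, m = 2, params = elastic_params()) {
  nodes <- cbind(seq_len(n) - 1, matrix(0, n, m - 1))
  principal_graph(nodes, cbind(seq_len(n - 1), seq_len(n - 1) + 1L), params)
}

# Y graph: center at origin, three unit arms along fixed directions
y_graph <- function(arm_nodes = 1, m = 2) {
  dirs <- rbind(c(1, 0), c(-0.5, sqrt(3) / 2), c(-0.5, -sqrt(3) / 2))
  nodes <- matrix(0, 1, 2)
  edges <- NULL
  for (a in 1:3) {
    prev <- 1L
    for (s in seq_len(arm_nodes)) {
      nodes <- rbind(nodes, (s / arm_nodes) * dirs[a, ])
      edges <- rbind(edges, c(prev, nrow(nodes)))
      prev <- nrow(nodes)
    }
  }
  if (m > 2) nodes <- cbind(nodes, matrix(0, nrow(nodes), m - 2))
  principal_graph(nodes, edges)
}

# study-condition generators for topology/pseudotime recovery:
# 2 branches = path, 3 = Y star, 4 = cascaded double bifurcation
recovery_spec <- function(arms) {
  switch(as.character(arms),
    "2" = tree_spec(rbind(c(1, 2), c(1, 3)), arm_lengths = 1, m = 5,
                    sigma = 0.07, n_per_branch = 150),
    "3" = tree_spec_star(3, arm_lengths = 1, m = 5, sigma = 0.07,
                         n_per_branch = 120),
    "4" = tree_spec(rbind(c(1, 2), c(2, 3), c(2, 4), c(1, 5), c(1, 6)),
                    arm_lengths = 1, m = 5, sigma = 0.07, n_per_branch = 80))
}

recovery_nodes <- function(arms) c("2" = 20L, "3" = 24L, "4" = 28L)[[as.character(arms)]]

# independent brute-force segment oracle: the segment of an edge is its
# closure through degree-2 nodes; the decomposition is the set of closures
oracle_segments <- function(edges, n_nodes) {
  if (!nrow(edges)) return(list())
  deg <- tabulate(as.vector(edges), n_nodes)
  inc <- lapply(seq_len(n_nodes), function(v)
    which(edges[, 1] == v | edges[, 2] == v))
  closure <- function(e0) {
    seen <- e0
    repeat {
      front <- unique(unlist(lapply(seen, function(e) {
        out <- integer(0)
        for (v in edges[e, ]) if (deg[v] == 2) out <- c(out, inc[[v]])
        out
      })))
      new <- setdiff(front, seen)
      if (!length(new)) break
      seen <- c(seen, new)
    }
    sort(seen)
  }
  unique(lapply(seq_len(nrow(edges)), closure))
}

# edge set of a segment's node path, as a sorted key for comparison
segment_edge_key <- function(path, edges) {
  if (length(path) < 2) return(integer(0))
  steps <- cbind(path[-length(path)], path[-1])
  sort(vapply(seq_len(nrow(steps)), function(r)
    which((edges[, 1] == steps[r, 1] & edges[, 2] == steps[r, 2]) |
          (edges[, 1] == steps[r, 2] & edges[, 2] == steps[r, 1]))[1],
    integer(1)))
}

# all labelled trees on n nodes via Pruefer sequences
pruefer_trees <- function(n) {
  if (n == 1) return(list(matrix(integer(0), 0, 2)))
  if (n == 2) return(list(matrix(c(1L, 2L), 1)))
  seqs <- expand.grid(rep(list(seq_len(n)), n - 2))
  lapply(seq_len(nrow(seqs)), function(i) {
    prf <- as.integer(seqs[i, ])
    degree <- rep(1L, n) + tabulate(prf, n)
    edges <- matrix(0L, n - 1, 2)
    for (k in seq_along(prf)) {
      leaf <- which(degree == 1L)[1]
      edges[k, ] <- c(leaf, prf[k])
      degree[leaf] <- degree[leaf] - 1L
      degree[prf[k]] <- degree[prf[k]] - 1L
    }
    edges[n - 1, ] <- which(degree == 1L)
    edges
  })
}
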