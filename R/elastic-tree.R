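#' Elastic parameters of a principal graph
#'
#' @param lambda Edge-stretching elasticity modulus (> 0): penalises the
#'   squared length of every edge, keeping edges short and near-equidistant.
#' @param mu Star-bending elasticity modulus (>= 0): penalises the squared
#'   deviation of each star centre from the mean of its neighbours
#'   (harmonicity).
#' @param alpha Topological-complexity penalty (>= 0): edges attached to a
#'   node of degree `d > 2` have their stretching modulus raised to
#'   `lambda + alpha * (d - 2)`, discouraging high-order branchings.
#' @param R0 Trimming radius (> 0, may be `Inf`): points farther than `R0`
#'   from every node contribute a constant `R0^2` to the approximation term
#'   and do not attract nodes.
#' @return An object of class `elastic_params`.
#' @export
elastic_params <- function(lambda = 0.05, mu = 0.1, alpha = 0.01, R0 = Inf) {
  stopifnot(lambda > 0, mu >= 0, alpha >= 0, R0 > 0)
  structure(list(lambda = lambda, mu = mu, alpha = alpha, R0 = R0),
            class = "elastic_params")
}

#' Principal graph: nodes embedded in data space plus an edge list
#'
#' @param nodes Numeric `N x m` matrix of node positions.
#' @param edges Integer `E x 2` matrix of undirected edges (1-based node
#'   indices).
#' @param params An [elastic_params()] object.
#' @return An object of class `principal_graph`.
#' @export
principal_graph <- function(nodes, edges, params = elastic_params()) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  if (!all(is.finite(nodes))) stopf("node positions must be finite")
  if (length(edges) == 0) {
    edges <- matrix(integer(0), 0, 2)
  } else {
    edges <- as.matrix(edges)
    storage.mode(edges) <- "integer"
  }
  stopifnot(ncol(edges) == 2)
  if (nrow(edges) && (max(edges) > nrow(nodes) || min(edges) < 1))
    stopf("edge indices out of range")
  if (nrow(edges) && any(edges[, 1] == edges[, 2])) stopf("self-loops not allowed")
  structure(list(nodes = nodes, edges = edges, params = params),
            class = "principal_graph")
}

#' @export
print.principal_graph <- function(x, ...) {
  dg <- graph_degrees(x)
  cat(sprintf("<principal_graph> %d nodes (%d leaves, %d branching), %d edges in %d-D\n",
              nrow(x$nodes), sum(dg <= 1), sum(dg > 2), nrow(x$edges),
              ncol(x$nodes)))
  invisible(x)
}

#' Node degrees of a principal graph
#' @param G A [principal_graph()].
#' @return Integer vector of degrees.
#' @export
graph_degrees <- function(G) {
  tabulate(as.vector(G$edges), nrow(G$nodes))
}

as_igraph <- function(G) {
  igraph::add_edges(igraph::make_empty_graph(nrow(G$nodes), directed = FALSE),
                    as.vector(t(G$edges)))
}

graph_is_tree <- function(G) {
  n <- nrow(G$nodes)
  if (nrow(G$edges) != n - 1) return(FALSE)
  igraph::is_connected(as_igraph(G))
}

# per-edge penalised stretching modulus (branching penalty)
lambda_penalized <- function(G) {
  if (!nrow(G$edges)) return(numeric(0))
  dg <- graph_degrees(G)
  d1 <- dg[G$edges[, 1]]; d2 <- dg[G$edges[, 2]]
  G$params$lambda + G$params$alpha * (pmax(2, d1, d2) - 2)
}

#' Assign each data point to its nearest graph node
#'
#' Ties are broken toward the lowest node index; points farther than the
#' trimming radius `R0` from every node are flagged as trimmed.
#'
#' @param X Data matrix (rows are observations).
#' @param G A [principal_graph()].
#' @return List with `assignment` (node index per point), `dist2` (squared
#'   distance to the assigned node), `trimmed` (logical).
#' @export
partition_points <- function(X, G) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == ncol(G$nodes))
  d2 <- cross_dist2(X, G$nodes)
  assignment <- max.col(-d2, ties.method = "first")
  dist2 <- d2[cbind(seq_len(nrow(X)), assignment)]
  list(assignment = assignment, dist2 = dist2,
       trimmed = dist2 > G$params$R0^2)
}

#' Elastic energy of a principal graph on a dataset
#'
#' The optimisation target is `U = MSD + U_E + U_R`:
#' * `MSD`: mean over points of the squared distance to the nearest node,
#'   trimmed at `R0^2`;
#' * `U_E`: sum over edges of the penalised stretching modulus times the
#'   squared edge length (edges at a node of degree `d > 2` are penalised by
#'   `alpha * (d - 2)` extra);
#' * `U_R`: `mu` times the sum over stars (nodes of degree >= 2) of the
#'   squared deviation of the centre from the mean of its neighbours.
#'
#' @param G A [principal_graph()] whose node dimension matches `X`.
#' @param X Data matrix.
#' @param partition Optional precomputed [partition_points()] result.
#' @return Named list `U`, `MSD`, `U_E`, `U_R`.
#' @export
graph_energy <- function(G, X, partition = NULL) {
  if (!nrow(G$nodes)) stopf("empty graph")
  X <- as.matrix(X)
  if (is.null(partition)) partition <- partition_points(X, G)
  msd <- mean(pmin(partition$dist2, G$params$R0^2))
  ue <- 0
  if (nrow(G$edges)) {
    dl <- G$nodes[G$edges[, 1], , drop = FALSE] -
          G$nodes[G$edges[, 2], , drop = FALSE]
    ue <- sum(lambda_penalized(G) * rowSums(dl^2))
  }
  ur <- 0
  dg <- graph_degrees(G)
  for (c_ in which(dg >= 2)) {
    nb <- neighbors_of(G, c_)
    dev <- G$nodes[c_, ] - colMeans(G$nodes[nb, , drop = FALSE])
    ur <- ur + sum(dev^2)
  }
  ur <- G$params$mu * ur
  list(U = msd + ue + ur, MSD = msd, U_E = ue, U_R = ur)
}

neighbors_of <- function(G, i) {
  c(G$edges[G$edges[, 1] == i, 2], G$edges[G$edges[, 2] == i, 1])
}

# quadratic-form system matrix for node-position optimisation at fixed
# partition: solve A Phi = B, one linear system shared by all coordinates
elastic_system <- function(G, X, assignment, trimmed) {
  n_nodes <- nrow(G$nodes)
  n <- nrow(X)
  use <- !trimmed
  counts <- tabulate(assignment[use], n_nodes)
  A <- diag(counts / n, n_nodes)
  lam <- lambda_penalized(G)
  for (e in seq_len(nrow(G$edges))) {
    a <- G$edges[e, 1]; b <- G$edges[e, 2]
    A[a, a] <- A[a, a] + lam[e]; A[b, b] <- A[b, b] + lam[e]
    A[a, b] <- A[a, b] - lam[e]; A[b, a] <- A[b, a] - lam[e]
  }
  dg <- graph_degrees(G)
  for (c_ in which(dg >= 2)) {
    nb <- neighbors_of(G, c_)
    u <- numeric(n_nodes)
    u[c_] <- 1; u[nb] <- u[nb] - 1 / length(nb)
    A <- A + G$params$mu * tcrossprod(u)
  }
  B <- matrix(0, n_nodes, ncol(X))
  for (j in unique(assignment[use])) {
    B[j, ] <- colSums(X[use & assignment == j, , drop = FALSE]) / n
  }
  list(A = A, B = B)
}

#' Optimise node positions at fixed topology (splitting algorithm)
#'
#' Alternates (a) partitioning the points to nearest nodes and (b) the exact
#' minimisation of the elastic energy over all node positions at fixed
#' partition, which is a quadratic problem solved as one linear system.
#' Both half-steps cannot increase the energy, so the energy trace is
#' non-increasing and the iteration converges.
#'
#' @param G A [principal_graph()].
#' @param X Data matrix.
#' @param tol Relative energy-decrease threshold for stopping.
#' @param max_iter Maximum number of partition/optimise iterations.
#' @return List with `graph` (updated node positions), `trace` (energy `U`
#'   per iteration), `energy` (final component list), `partition`.
#' @export
fit_node_positions <- function(G, X, tol = 1e-6, max_iter = 200L) {
  X <- as.matrix(X)
  part <- partition_points(X, G)
  en <- graph_energy(G, X, part)
  trace <- en$U
  for (it in seq_len(max_iter)) {
    sys <- elastic_system(G, X, part$assignment, part$trimmed)
    phi <- tryCatch(solve(sys$A, sys$B), error = function(e) {
      if (G$params$lambda == 0 && G$params$mu == 0)
        stopf("singular node-position system (lambda = mu = 0 with empty nodes)")
      solve(sys$A + diag(1e-12, nrow(sys$A)), sys$B)
    })
    G$nodes <- phi
    part <- partition_points(X, G)
    en <- graph_energy(G, X, part)
    trace <- c(trace, en$U)
    prev <- trace[length(trace) - 1]
    if (prev - en$U < tol * max(prev, .Machine$double.eps)) break
  }
  list(graph = G, trace = trace, energy = en, partition = part)
}

# candidate structures one grammar application away from G:
#  "add a node to a node" for every node, "bisect an edge" for every edge
grammar_candidates <- function(G, X, partition) {
  cands <- list()
  n_nodes <- nrow(G$nodes)
  mean_len <- if (nrow(G$edges)) {
    dl <- G$nodes[G$edges[, 1], , drop = FALSE] -
          G$nodes[G$edges[, 2], , drop = FALSE]
    mean(sqrt(rowSums(dl^2)))
  } else 1
  for (j in seq_len(n_nodes)) {
    pts <- X[partition$assignment == j & !partition$trimmed, , drop = FALSE]
    offset <- if (nrow(pts)) colMeans(pts) - G$nodes[j, ] else numeric(ncol(X))
    if (sum(offset^2) < 1e-24) {
      # fallback: small jitter along the node's dominant local direction
      nb <- neighbors_of(G, j)
      dir <- if (length(nb)) {
        G$nodes[j, ] - colMeans(G$nodes[nb, , drop = FALSE])
      } else stats::rnorm(ncol(X))
      if (sum(dir^2) < 1e-24) dir <- stats::rnorm(ncol(X))
      offset <- 0.1 * mean_len * dir / sqrt(sum(dir^2))
    }
    cands[[length(cands) + 1L]] <- principal_graph(
      rbind(G$nodes, G$nodes[j, ] + offset),
      rbind(G$edges, c(j, n_nodes + 1L)), G$params)
  }
  for (e in seq_len(nrow(G$edges))) {
    a <- G$edges[e, 1]; b <- G$edges[e, 2]
    mid <- (G$nodes[a, ] + G$nodes[b, ]) / 2
    cands[[length(cands) + 1L]] <- principal_graph(
      rbind(G$nodes, mid),
      rbind(G$edges[-e, , drop = FALSE],
            c(a, n_nodes + 1L), c(n_nodes + 1L, b)),
      G$params)
  }
  cands
}

#' Learn an elastic principal tree by topological grammar search
#'
#' Starting from a 2-node seed placed on the first principal direction of the
#' data, the tree grows one node at a time: every structure reachable by a
#' single grammar operation ("add a node to a node" or "bisect an edge") is
#' fitted with a cheap run of [fit_node_positions()] and the candidate with
#' the lowest elastic energy is accepted, until `n_nodes` nodes are reached.
#' The accepted graph is finally polished with a tighter fit.
#'
#' @param X Data matrix (>= `n_nodes` rows).
#' @param n_nodes Target number of nodes (>= 2).
#' @param params An [elastic_params()]; the defaults (`lambda = 0.05`,
#'   `mu = 0.1`, `alpha = 0.01`, `R0 = Inf`) suit standardised clinical data.
#' @param seed Integer seed governing the (rarely used) jitter fallback when
#'   a grammar candidate has no data-driven placement.
#' @param candidate_tol,candidate_iter Fitting budget per candidate.
#' @param final_tol,final_iter Fitting budget for the final polish.
#' @return List with `graph` (the fitted [principal_graph()]) and `report`
#'   (class `fit_report`): per-step energy components `U`, `MSD`, `U_E`,
#'   `U_R`, the per-step candidate energies, final node count, explained
#'   variance and the final point partition.
#' @export
grow_tree <- function(X, n_nodes = 50L, params = elastic_params(), seed = 1L,
                      candidate_tol = 1e-4, candidate_iter = 20L,
                      final_tol = 1e-6, final_iter = 200L) {
  X <- as.matrix(X)
  if (!is_count(n_nodes) || n_nodes < 2) stopf("n_nodes must be >= 2")
  if (nrow(X) < n_nodes)
    stopf("need at least n_nodes = %d data points, got %d", n_nodes, nrow(X))
  with_seed(seed, {
    # deterministic 2-node seed on the first principal direction
    ctr <- colMeans(X)
    v1 <- svd(sweep(X, 2, ctr), nu = 0, nv = 1)$v[, 1]
    s <- stats::sd(drop(sweep(X, 2, ctr) %*% v1)) / 2
    G <- principal_graph(rbind(ctr - s * v1, ctr + s * v1),
                         matrix(c(1L, 2L), 1), params)
    fit <- fit_node_positions(G, X, final_tol, final_iter)
    G <- fit$graph
    steps <- list(c(unlist(fit$energy), n_nodes = 2))
    cand_energies <- list()
    while (nrow(G$nodes) < n_nodes) {
      cands <- grammar_candidates(G, X, fit$partition)
      fits <- lapply(cands, function(cg)
        fit_node_positions(cg, X, tol = candidate_tol,
                           max_iter = candidate_iter))
      us <- vapply(fits, function(f) f$energy$U, numeric(1))
      best <- which.min(us)
      fit <- fits[[best]]
      G <- fit$graph
      cand_energies[[length(cand_energies) + 1L]] <-
        list(accepted = best, energies = us)
      steps[[length(steps) + 1L]] <-
        c(unlist(fit$energy), n_nodes = nrow(G$nodes))
    }
    fit <- fit_node_positions(G, X, final_tol, final_iter)
    G <- fit$graph
    trace <- as.data.frame(do.call(rbind, steps))
    report <- structure(
      list(trace = trace, candidate_energies = cand_energies,
           n_nodes = nrow(G$nodes),
           explained_variance = explained_variance(G, X),
           partition = fit$partition, final_energy = fit$energy),
      class = "fit_report")
    list(graph = G, report = report)
  })
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("<fit_report> %d nodes; final U = %.5g (MSD %.5g); explained variance %.1f%%\n",
              x$n_nodes, x$final_energy$U, x$final_energy$MSD,
              100 * x$explained_variance))
  invisible(x)
}

#' Prune single-edge terminal segments of a tree
#'
#' Removes every leaf that hangs by a single edge directly off a branching
#' node (a terminal segment of one edge), repeating until none remain.
#' Spurious one-edge branches are a known artefact of grammar-grown trees.
#'
#' @param G A [principal_graph()] tree.
#' @return The pruned [principal_graph()]; warns if pruning collapses the
#'   tree to a single node.
#' @export
prune_tree <- function(G) {
  stopifnot(graph_is_tree(G))
  repeat {
    dg <- graph_degrees(G)
    drop <- integer(0)
    for (l in which(dg == 1)) {
      nb <- neighbors_of(G, l)
      if (dg[nb] >= 3) drop <- c(drop, l)
    }
    if (!length(drop)) break
    keep <- setdiff(seq_len(nrow(G$nodes)), drop)
    remap <- match(seq_len(nrow(G$nodes)), keep)
    E <- G$edges[!(G$edges[, 1] %in% drop | G$edges[, 2] %in% drop), ,
                 drop = FALSE]
    E[] <- remap[E]
    G <- principal_graph(G$nodes[keep, , drop = FALSE], E, G$params)
    if (nrow(G$nodes) < 2 || !nrow(G$edges)) {
      warnf("pruning collapsed the tree to %d node(s)", nrow(G$nodes))
      break
    }
  }
  G
}

#' Extend terminal edges so extreme points project onto edge interiors
#'
#' Each leaf node is moved outward along the direction of its terminal edge
#' to the orthogonal projection of the farthest point assigned to it, so the
#' data at the end of a branch project onto the edge rather than piling up
#' on the leaf node.
#'
#' @param G A fitted [principal_graph()] tree.
#' @param X Data matrix.
#' @return The extended [principal_graph()].
#' @export
extend_leaves <- function(G, X) {
  X <- as.matrix(X)
  part <- partition_points(X, G)
  dg <- graph_degrees(G)
  for (l in which(dg == 1)) {
    nb <- neighbors_of(G, l)
    dir <- G$nodes[l, ] - G$nodes[nb, ]
    nrm <- sqrt(sum(dir^2))
    if (nrm == 0) next
    dir <- dir / nrm
    pts <- X[part$assignment == l & !part$trimmed, , drop = FALSE]
    if (!nrow(pts)) next
    t_ <- max(sweep(pts, 2, G$nodes[l, ]) %*% dir)
    if (t_ > 0) G$nodes[l, ] <- G$nodes[l, ] + t_ * dir
  }
  G
}

#' Project points onto a principal graph as a piecewise-linear manifold
#'
#' Each point is projected onto the closest point of the union of linear
#' edge segments; the projection is reported as the owning edge `p`, the
#' position `eps` in `[0, 1]` along that edge from `E^p(0)` to `E^p(1)`, the
#' projected coordinates and the squared residual.  Ties across edges are
#' broken toward the lowest edge index.
#'
#' @param X Data matrix (a single point may be given as a vector).
#' @param G A [principal_graph()] with at least one edge.
#' @return A data.frame with columns `edge`, `eps`, `residual2`; the matrix
#'   of projected coordinates is attached as attribute `"coords"`.
#' @export
project_points <- function(X, G) {
  if (is.null(dim(X))) X <- matrix(X, 1)
  X <- as.matrix(X)
  if (!nrow(G$edges)) stopf("graph has no edges to project on")
  n <- nrow(X); ne <- nrow(G$edges)
  t_all <- matrix(0, n, ne); d2_all <- matrix(Inf, n, ne)
  for (e in seq_len(ne)) {
    a <- G$nodes[G$edges[e, 1], ]; b <- G$nodes[G$edges[e, 2], ]
    v <- b - a
    len2 <- sum(v^2)
    t_ <- if (len2 == 0) rep(0, n) else
      pmin(1, pmax(0, (sweep(X, 2, a) %*% v) / len2))
    proj <- outer(drop(t_), v) + rep(a, each = n)
    d2_all[, e] <- rowSums((X - proj)^2)
    t_all[, e] <- t_
  }
  edge <- max.col(-d2_all, ties.method = "first")
  eps <- t_all[cbind(seq_len(n), edge)]
  res2 <- d2_all[cbind(seq_len(n), edge)]
  a <- G$nodes[G$edges[edge, 1], , drop = FALSE]
  b <- G$nodes[G$edges[edge, 2], , drop = FALSE]
  coords <- a + (b - a) * eps
  out <- data.frame(edge = edge, eps = eps, residual2 = res2)
  attr(out, "coords") <- coords
  out
}

#' @rdname project_points
#' @param x A single point (vector).
#' @export
project_point <- function(x, G) {
  pr <- project_points(matrix(x, 1), G)
  list(edge = pr$edge, eps = pr$eps, coords = drop(attr(pr, "coords")),
       residual2 = pr$residual2)
}

#' Fraction of data variance explained by a principal graph
#'
#' `1 - sum(residual^2) / sum(|x - mean|^2)`, residuals taken from
#' [project_points()] (or squared node distances for an edgeless graph).
#'
#' @param G A [principal_graph()].
#' @param X Data matrix.
#' @return Fraction in `[0, 1]` (can be negative for a bad graph).
#' @export
explained_variance <- function(G, X) {
  X <- as.matrix(X)
  tot <- sum(sweep(X, 2, colMeans(X))^2)
  if (tot == 0) stopf("zero total variance")
  res <- if (nrow(G$edges)) sum(project_points(X, G)$residual2)
         else sum(partition_points(X, G)$dist2)
  1 - res / tot
}

#' Serialize / read a principal graph as JSON
#'
#' The JSON object holds `nodes` (list of coordinate vectors), `edges`
#' (1-based pairs), the elastic `params` and a free-form `provenance` entry.
#'
#' @param G A [principal_graph()].
#' @param path Output (input) path.
#' @param provenance Optional list stored alongside the graph.
#' @return `write_principal_graph`: `G` invisibly; `read_principal_graph`:
#'   the graph, with provenance in attribute `"provenance"`.
#' @export
write_principal_graph <- function(G, path, provenance = NULL) {
  jsonlite::write_json(
    list(nodes = unname(split(G$nodes, row(G$nodes))),
         edges = unname(split(G$edges, row(G$edges))),
         params = unclass(G$params),
         provenance = provenance),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(G)
}

#' @rdname write_principal_graph
#' @export
read_principal_graph <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  prm <- do.call(elastic_params, as.list(obj$params))
  as_mat <- function(x, ncol) {
    if (is.matrix(x)) x
    else if (is.list(x) && length(x)) do.call(rbind, x)
    else if (length(x)) matrix(x, ncol = ncol)
    else matrix(integer(0), 0, ncol)
  }
  nodes <- as_mat(obj$nodes, 1)
  edges <- as_mat(obj$edges, 2)
  G <- principal_graph(nodes, edges, prm)
  attr(G, "provenance") <- obj$provenance
  G
}
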