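#' Specification of a synthetic branching dataset
#'
#' Describes a ground-truth tree embedded in `m`-dimensional space, the
#' sampling of points along its arms, and optional degradation of coordinates
#' to ordinal/binary levels and injection of missingness.  The generator is
#' the test bed for the whole pipeline: it produces data condensed along a
#' noisy embedded tree together with the true branch label and arc-length
#' pseudo-time of every observation.
#'
#' @param topology Integer edge list (2-column matrix or data.frame) over
#'   abstract nodes `1..K`; must form a tree.  Node `root` is the origin of
#'   ground-truth pseudo-time.
#' @param arm_lengths Numeric vector, one embedded length per edge.
#' @param m Embedding dimension.
#' @param sigma Isotropic Gaussian noise s.d. added to each point.
#' @param n_per_branch Points sampled uniformly along each edge (recycled).
#' @param root Abstract node id of the root (default 1).
#' @param degrade Optional degradation plan; see [degrade_to_mixed()].
#' @param missing Optional missingness plan: a list
#'   `list(mechanism = "uniform"|"column_block", fraction =, columns =)`.
#' @return An object of class `tree_spec`.
#' @export
tree_spec <- function(topology, arm_lengths, m = 2, sigma = 0.05,
                      n_per_branch = 100, root = 1L,
                      degrade = NULL, missing = NULL) {
  topology <- as.matrix(topology)
  storage.mode(topology) <- "integer"
  stopifnot(ncol(topology) == 2L, nrow(topology) >= 1L)
  k <- max(topology)
  g <- igraph::graph_from_edgelist(topology, directed = FALSE)
  if (igraph::vcount(g) != k || igraph::ecount(g) != k - 1L ||
      !igraph::is_connected(g))
    stopf("topology must be a tree over nodes 1..K")
  arm_lengths <- rep_len(as.numeric(arm_lengths), nrow(topology))
  n_per_branch <- rep_len(as.integer(n_per_branch), nrow(topology))
  stopifnot(all(arm_lengths > 0), sigma >= 0, m >= 2, all(n_per_branch >= 1))
  structure(list(topology = topology, arm_lengths = arm_lengths, m = m,
                 sigma = sigma, n_per_branch = n_per_branch,
                 root = as.integer(root), degrade = degrade,
                 missing = missing),
            class = "tree_spec")
}

#' Star-shaped tree specification (k arms radiating from a center)
#' @param arms Number of arms (>= 2).
#' @param ... Passed to [tree_spec()].
#' @export
tree_spec_star <- function(arms = 3, ...) {
  stopifnot(arms >= 2)
  tree_spec(cbind(1L, seq_len(arms) + 1L), ...)
}

# seeded unit directions for the outgoing edges of one node, kept at pairwise
# angle > 60 degrees from each other and from already placed directions
pick_directions <- function(n_new, existing, m) {
  dirs <- existing
  out <- matrix(0, n_new, m)
  for (i in seq_len(n_new)) {
    best <- NULL; best_sep <- -Inf
    for (try in seq_len(200L)) {
      d <- stats::rnorm(m)
      d <- d / sqrt(sum(d^2))
      sep <- if (nrow(dirs)) min(acos(pmin(1, pmax(-1, dirs %*% d)))) else pi
      if (sep > best_sep) { best <- d; best_sep <- sep }
      if (best_sep > pi / 3) break
    }
    out[i, ] <- best
    dirs <- rbind(dirs, best)
  }
  out
}

#' Generate a mixed-type dataset condensed along a noisy embedded tree
#'
#' Embeds the abstract tree of `spec` in `m` dimensions (root at the origin,
#' arms in seeded well-separated directions), samples points uniformly along
#' each arm, adds isotropic Gaussian noise, then applies the degradation and
#' missingness plans if present.  Ground truth (branch label and arc-length
#' pseudo-time from the root) is recorded before degradation.
#'
#' @param spec A [tree_spec()].
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return List with elements `dataset` (a [mixed_dataset()]), `X` (the clean
#'   numeric coordinates before degradation/missingness), `truth` (data.frame
#'   with `branch` and `pseudotime`), and `node_positions`.
#' @export
generate_branching_dataset <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "tree_spec"))
  with_seed(seed, {
    k <- max(spec$topology)
    pos <- matrix(NA_real_, k, spec$m)
    pos[spec$root, ] <- 0
    # orient edges away from root, BFS
    g <- igraph::graph_from_edgelist(spec$topology, directed = FALSE)
    bfs <- igraph::bfs(g, root = spec$root, father = TRUE)
    order <- as.integer(bfs$order)
    father <- as.integer(bfs$father)
    edge_of <- function(a, b) which((spec$topology[, 1] == a & spec$topology[, 2] == b) |
                                    (spec$topology[, 1] == b & spec$topology[, 2] == a))
    dir_in <- matrix(0, k, spec$m)         # incoming direction at each node
    arc_at_node <- numeric(k)              # arc length root -> node
    edge_parent <- integer(nrow(spec$topology))
    edge_dir <- matrix(0, nrow(spec$topology), spec$m)
    for (v in order) {
      if (v == spec$root) next
      p <- father[v]
      # keep new arm > 60 degrees away from the reversed incoming edge at p
      # (no doubling back) and from arms already placed at p
      sibs <- which(edge_parent != 0L & edge_parent == p)
      anchors <- rbind(if (sum(dir_in[p, ]^2) > 0) -dir_in[p, , drop = FALSE],
                       if (length(sibs)) edge_dir[sibs, , drop = FALSE])
      if (is.null(anchors)) anchors <- matrix(0, 0, spec$m)
      d <- pick_directions(1L, anchors, spec$m)
      e <- edge_of(p, v)
      edge_parent[e] <- p
      edge_dir[e, ] <- d
      pos[v, ] <- pos[p, ] + spec$arm_lengths[e] * d
      dir_in[v, ] <- d
      arc_at_node[v] <- arc_at_node[p] + spec$arm_lengths[e]
    }
    # sample points on each edge
    Xs <- vector("list", nrow(spec$topology))
    truths <- vector("list", nrow(spec$topology))
    for (e in seq_len(nrow(spec$topology))) {
      p <- edge_parent[e]
      n <- spec$n_per_branch[e]
      t <- stats::runif(n, 0, spec$arm_lengths[e])
      base <- pos[rep(p, n), , drop = FALSE] + outer(t, edge_dir[e, ])
      Xs[[e]] <- base
      truths[[e]] <- data.frame(branch = e, pseudotime = arc_at_node[p] + t)
    }
    X <- do.call(rbind, Xs)
    truth <- do.call(rbind, truths)
    if (spec$sigma > 0)
      X <- X + matrix(stats::rnorm(length(X), sd = spec$sigma), nrow(X))
    rownames(X) <- truth$row_id <- sprintf("obs%04d", seq_len(nrow(X)))
    colnames(X) <- sprintf("x%d", seq_len(ncol(X)))

    ds <- if (is.null(spec$degrade)) {
      continuous_dataset(X)
    } else {
      degrade_to_mixed(X, spec$degrade)
    }
    if (!is.null(spec$missing)) {
      mp <- spec$missing
      ds <- inject_missing(ds, mechanism = mp$mechanism,
                           fraction = mp$fraction,
                           seed = stats::runif(1, 1, 2^30),
                           columns = mp$columns)
    }
    list(dataset = ds, X = X, truth = truth, node_positions = pos)
  })
}

# wrap a numeric matrix as an all-continuous mixed_dataset
continuous_dataset <- function(X) {
  df <- as.data.frame(X)
  meta <- lapply(colnames(X), variable_meta, kind = "continuous")
  mixed_dataset(df, meta)
}

#' Degrade continuous columns to ordinal/binary levels by binning
#'
#' Selected columns are discretized with strictly increasing interior bin
#' edges; the resulting level labels `"0","1",...` preserve the numeric
#' order, so the original latent ordering is recoverable by quantification.
#'
#' @param X Numeric matrix.
#' @param plan List of per-column instructions
#'   `list(column =, kind = "ordinal"|"binary", breaks =)` where `breaks` are
#'   the interior bin edges (a single break for binary), or
#'   `n_levels =` to use equal-mass quantile breaks.
#' @return A [mixed_dataset()] where planned columns are nominal and all
#'   others remain continuous.
#' @export
degrade_to_mixed <- function(X, plan) {
  stopifnot(is.matrix(X), is.numeric(X))
  df <- as.data.frame(X)
  meta <- lapply(colnames(X), variable_meta, kind = "continuous")
  names(meta) <- colnames(X)
  for (item in plan) {
    j <- item$column
    if (is.character(j)) j <- match(j, colnames(X))
    kind <- item$kind %||% "ordinal"
    breaks <- item$breaks
    if (is.null(breaks)) {
      nl <- item$n_levels %||% if (kind == "binary") 2L else 4L
      breaks <- stats::quantile(X[, j], probs = seq_len(nl - 1) / nl,
                                names = FALSE)
    }
    if (is.unsorted(breaks, strictly = TRUE))
      stopf("column %s: bin edges must be strictly increasing", colnames(X)[j])
    full <- c(-Inf, breaks, Inf)
    counts <- table(cut(X[, j], full))
    if (any(counts == 0))
      warnf("column %s: %d bin(s) cover no data", colnames(X)[j],
            sum(counts == 0))
    lev <- as.character(seq_len(length(breaks) + 1L) - 1L)
    code <- lev[findInterval(X[, j], breaks) + 1L]
    df[[j]] <- code
    meta[[j]] <- variable_meta(colnames(X)[j],
                               kind = if (kind == "binary") "binary" else "ordinal",
                               levels = lev)
  }
  mixed_dataset(df, meta)
}

#' Inject missing values into a dataset
#'
#' Emulates the non-uniform missingness of real clinical tables with two
#' mechanisms: `"uniform"` (every cell independently missing with probability
#' `fraction`) and `"column_block"` (missingness concentrated in the chosen
#' columns at rate `fraction`).
#'
#' @param ds A [mixed_dataset()].
#' @param mechanism `"uniform"` or `"column_block"`.
#' @param fraction Missing probability in `[0, 1)`.
#' @param seed Integer seed.
#' @param columns Columns targeted by `"column_block"` (names or indices).
#' @return The degraded [mixed_dataset()].
#' @export
inject_missing <- function(ds, mechanism = c("uniform", "column_block"),
                           fraction, seed = 1L, columns = NULL) {
  stopifnot(inherits(ds, "mixed_dataset"), is_fraction(fraction), fraction < 1)
  mechanism <- match.arg(mechanism)
  with_seed(seed, {
    df <- ds$values
    n <- nrow(df)
    if (mechanism == "uniform") {
      hit <- matrix(stats::runif(n * ncol(df)) < fraction, n, ncol(df))
      for (j in seq_along(df)) df[[j]][hit[, j]] <- NA
    } else {
      if (is.null(columns)) stopf("column_block requires 'columns'")
      if (is.character(columns)) columns <- match(columns, colnames(df))
      for (j in columns) df[[j]][stats::runif(n) < fraction] <- NA
    }
    mixed_dataset(df, ds$meta, row_ids = ds$row_ids)
  })
}
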