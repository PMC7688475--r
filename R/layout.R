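#' Two-dimensional metro-map layout of a principal graph
#'
#' Embeds the graph in the plane with the Kamada-Kawai force-directed
#' algorithm, whose stress objective makes pairwise Euclidean distances
#' approximate the graph geodesic distances.  Disconnected components are
#' laid out separately and tiled side by side.  The result is deterministic
#' for a fixed seed.
#'
#' @param G A [principal_graph()].
#' @param seed Integer seed.
#' @return An object of class `graph_layout`: list with `coords`
#'   (`N x 2` matrix) and `seed`.
#' @export
layout_graph <- function(G, seed = 1L) {
  g <- as_igraph(G)
  comp <- igraph::components(g)
  coords <- matrix(0, nrow(G$nodes), 2)
  with_seed(seed, {
    x_shift <- 0
    for (ci in seq_len(comp$no)) {
      vs <- which(comp$membership == ci)
      sub <- igraph::induced_subgraph(g, vs)
      xy <- if (length(vs) == 1) matrix(0, 1, 2) else
        igraph::layout_with_kk(sub)
      xy <- sweep(xy, 2, apply(xy, 2, min))
      xy[, 1] <- xy[, 1] + x_shift
      x_shift <- max(xy[, 1]) + 1
      coords[vs, ] <- xy
    }
  })
  if (!all(is.finite(coords))) stopf("layout produced non-finite coordinates")
  structure(list(coords = coords, seed = seed), class = "graph_layout")
}

embedded_edge_lengths <- function(G, layout) {
  dl <- layout$coords[G$edges[, 1], , drop = FALSE] -
        layout$coords[G$edges[, 2], , drop = FALSE]
  sqrt(rowSums(dl^2))
}

#' Place data points around the embedded graph
#'
#' Each observation sits at its projection abscissa on its owning embedded
#' edge and is displaced perpendicularly, on a seeded random side, by
#' `scattering` times its projection residual in the original space.  The
#' default scattering makes the median displacement equal to 25% of the
#' median embedded edge length.
#'
#' @param X Data matrix in the original space.
#' @param G A [principal_graph()].
#' @param layout A [layout_graph()] result.
#' @param scattering Residual-to-displacement proportionality constant
#'   (default: auto, see above).
#' @param seed Integer seed for the side choice.
#' @return A data.frame of class `point_layout` with columns `x`, `y`,
#'   `edge`, `eps`, `side`, `residual`; the scattering used is attached as
#'   attribute `"scattering"`.
#' @export
place_points <- function(X, G, layout, scattering = NULL, seed = 1L) {
  X <- as.matrix(X)
  proj <- project_points(X, G)
  residual <- sqrt(proj$residual2)
  if (is.null(scattering)) {
    med_res <- stats::median(residual)
    scattering <- if (med_res > 0)
      0.25 * stats::median(embedded_edge_lengths(G, layout)) / med_res
    else 0
  }
  A <- layout$coords[G$edges[proj$edge, 1], , drop = FALSE]
  B <- layout$coords[G$edges[proj$edge, 2], , drop = FALSE]
  base <- A + (B - A) * proj$eps
  ev <- B - A
  ln <- pmax(sqrt(rowSums(ev^2)), .Machine$double.xmin)
  perp <- cbind(-ev[, 2], ev[, 1]) / ln
  side <- with_seed(seed, sample(c(-1, 1), nrow(X), replace = TRUE))
  coord <- base + perp * (side * scattering * residual)
  out <- data.frame(x = coord[, 1], y = coord[, 2], edge = proj$edge,
                    eps = proj$eps, side = side, residual = residual)
  attr(out, "scattering") <- scattering
  class(out) <- c("point_layout", "data.frame")
  out
}

#' Per-edge mean of a variable, for edge-width encoding
#'
#' Computes, for every edge, the mean value of a numeric (or binary 0/1)
#' variable over the observations projected onto it, normalised to
#' `[0, 1]` for use as an edge width.  Edges with no projected observations
#' are interpolated from the means of their incident nodes (points assigned
#' to each node by [partition_points()]).
#'
#' @param G A [principal_graph()].
#' @param X Data matrix.
#' @param var Numeric variable per observation (`NA` allowed, not all).
#' @return Data.frame with columns `edge`, `mean`, `width` (normalised to
#'   `[0, 1]`; constant variables give equal widths of 0.5).
#' @export
edge_trend <- function(G, X, var) {
  X <- as.matrix(X)
  var <- as.numeric(var)
  if (all(is.na(var))) stopf("variable is entirely missing")
  proj <- project_points(X, G)
  ne <- nrow(G$edges)
  means <- vapply(seq_len(ne), function(e) {
    v <- var[proj$edge == e]
    if (all(is.na(v)) || !length(v)) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  if (anyNA(means)) {
    part <- partition_points(X, G)
    node_mean <- vapply(seq_len(nrow(G$nodes)), function(j) {
      v <- var[part$assignment == j]
      if (!length(v) || all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
    node_mean[is.na(node_mean)] <- mean(var, na.rm = TRUE)
    for (e in which(is.na(means)))
      means[e] <- mean(node_mean[G$edges[e, ]])
  }
  rng <- range(means)
  width <- if (diff(rng) == 0) rep(0.5, ne) else
    (means - rng[1]) / diff(rng)
  data.frame(edge = seq_len(ne), mean = means, width = width)
}

#' Per-node class proportions (pie-chart summaries)
#'
#' For every graph node, the proportion of each class among the
#' observations assigned to it; the tabular form of per-node pie charts.
#'
#' @param G A [principal_graph()].
#' @param X Data matrix.
#' @param labels Class label per observation.
#' @return Data.frame with columns `node`, `class`, `n`, `proportion`.
#' @export
node_class_proportions <- function(G, X, labels) {
  part <- partition_points(as.matrix(X), G)
  tab <- table(node = part$assignment, class = labels)
  df <- as.data.frame(tab, responseName = "n")
  tot <- stats::ave(df$n, df$node, FUN = sum)
  df$proportion <- ifelse(tot > 0, df$n / tot, 0)
  df$node <- as.integer(as.character(df$node))
  df
}
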