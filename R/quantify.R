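#' Latent-Gaussian scores for an ordinal variable
#'
#' Univariate quantification assumes the ordered levels arise by binning a
#' latent standard-normal variable.  Level `i` with count `n_i` and
#' proportion `p_i = n_i / N` receives the score at the centre of its
#' cumulative probability mass,
#' `x_i = qnorm(sum(p_j, j < i) + p_i / 2)`.
#' Levels with zero count receive the score at their cumulative position.
#'
#' @param counts Non-negative per-level counts in level order; at least one
#'   must be positive.
#' @return Numeric scores, one per level, non-decreasing (strictly increasing
#'   over levels with positive counts).
#' @export
quantify_ordinal_univariate <- function(counts) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  if (sum(counts) == 0) stopf("all level counts are zero")
  p <- counts / sum(counts)
  cum <- c(0, cumsum(p))[seq_along(p)]
  stats::qnorm(cum + p / 2)
}

# per-variable quantification map from observed nominal values
quantification_map <- function(values, levels) {
  counts <- as.numeric(table(factor(values, levels = levels)))
  list(levels = levels, counts = counts,
       props = counts / max(1, sum(counts)),
       scores = quantify_ordinal_univariate(counts))
}

#' Dummy (one-hot) encoding of a categorical variable
#'
#' @param values Character vector of observed values (`NA` allowed).
#' @param levels Declared levels (`k >= 2`).
#' @param drop_first Drop the first level's column (`k - 1` encoding).
#' @return 0/1 numeric matrix with one column per kept level; a missing
#'   source entry is missing in every derived column.
#' @export
dummy_encode <- function(values, levels, drop_first = FALSE) {
  if (length(levels) < 2L) stopf("dummy encoding needs >= 2 levels")
  keep <- if (drop_first) levels[-1] else levels
  out <- vapply(keep, function(l) as.numeric(values == l),
                numeric(length(values)))
  out <- matrix(out, nrow = length(values),
                dimnames = list(NULL, keep))
  out[is.na(values), ] <- NA_real_
  out
}

#' Quantify a mixed-type dataset into a numeric matrix
#'
#' Ordinal and binary variables receive univariate latent-Gaussian scores
#' ([quantify_ordinal_univariate()]; binary variables are treated as 2-level
#' ordinals), categorical variables are dummy-encoded, continuous variables
#' pass through.  Missing entries stay `NA` in the numeric matrix, to be
#' filled by [svd_complete_impute()] or [svd_full_impute()].
#'
#' @param ds A [mixed_dataset()].
#' @param roles Which variable roles to include (default `"feature"`).
#' @param drop_first Passed to [dummy_encode()].
#' @return An object of class `quantified_matrix` with elements `values`
#'   (numeric matrix), `provenance` (per-column source variable, dummy level
#'   and kind), and `maps` (per ordinal/binary variable: levels, counts,
#'   proportions, scores).
#' @export
quantify_dataset <- function(ds, roles = "feature", drop_first = FALSE) {
  stopifnot(inherits(ds, "mixed_dataset"))
  meta <- Filter(function(m) m$role %in% roles, ds$meta)
  if (!length(meta)) stopf("no variables with role in {%s}",
                           paste(roles, collapse = ", "))
  cols <- list(); prov <- list(); maps <- list()
  for (m in meta) {
    v <- ds$values[[m$name]]
    if (m$kind == "continuous") {
      cols[[m$name]] <- matrix(v, ncol = 1, dimnames = list(NULL, m$name))
      prov[[m$name]] <- data.frame(column = m$name, source = m$name,
                                   level = NA_character_, kind = "continuous")
    } else if (m$kind == "categorical") {
      dm <- dummy_encode(v, m$levels, drop_first)
      colnames(dm) <- paste(m$name, colnames(dm), sep = "=")
      cols[[m$name]] <- dm
      prov[[m$name]] <- data.frame(column = colnames(dm), source = m$name,
                                   level = if (drop_first) m$levels[-1] else m$levels,
                                   kind = "dummy")
    } else {  # ordinal or binary: 2-level ordinal
      map <- quantification_map(v, m$levels)
      maps[[m$name]] <- map
      sc <- map$scores[match(v, m$levels)]
      cols[[m$name]] <- matrix(sc, ncol = 1, dimnames = list(NULL, m$name))
      prov[[m$name]] <- data.frame(column = m$name, source = m$name,
                                   level = NA_character_, kind = m$kind)
    }
  }
  values <- do.call(cbind, unname(cols))
  rownames(values) <- ds$row_ids
  structure(list(values = values,
                 provenance = do.call(rbind, unname(prov)),
                 maps = maps, center = NULL, scale = NULL),
            class = "quantified_matrix")
}

#' @export
print.quantified_matrix <- function(x, ...) {
  cat(sprintf("<quantified_matrix> %d x %d (%d ordinal/binary maps); %.1f%% missing\n",
              nrow(x$values), ncol(x$values), length(x$maps),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.quantified_matrix <- function(x) dim(x$values)

#' Extract the numeric matrix from a quantified_matrix
#' @param x A `quantified_matrix` (a bare matrix passes through).
#' @return Numeric matrix.
#' @export
qm_values <- function(x) {
  if (inherits(x, "quantified_matrix")) x$values
  else if (is.matrix(x)) x
  else stopf("expected a quantified_matrix or numeric matrix")
}

# weighted pool-adjacent-violators: non-decreasing fit to y with weights w
pava <- function(y, w) {
  # standard stack-based PAVA
  vals <- numeric(0); wts <- numeric(0); sizes <- integer(0)
  for (i in seq_along(y)) {
    cv <- y[i]; cw <- w[i]; cs <- 1L
    while (length(vals) && vals[length(vals)] >= cv) {
      k <- length(vals)
      cv <- (vals[k] * wts[k] + cv * cw) / (wts[k] + cw)
      cw <- wts[k] + cw
      cs <- sizes[k] + cs
      vals <- vals[-k]; wts <- wts[-k]; sizes <- sizes[-k]
    }
    vals <- c(vals, cv); wts <- c(wts, cw); sizes <- c(sizes, cs)
  }
  rep(vals, sizes)
}

# standardize columns to zero mean, unit population variance
standardize_pop <- function(x) {
  mu <- mean(x)
  sd_ <- sqrt(mean((x - mu)^2))
  if (sd_ == 0) return(NULL)
  (x - mu) / sd_
}

# J = sum over unordered column pairs of squared Pearson correlation
scaling_objective <- function(M) {
  R <- suppressWarnings(stats::cor(M))
  R[!is.finite(R)] <- 0
  (sum(R^2) - ncol(M)) / 2
}

#' Multivariate quantification of ordinal variables by optimal scaling
#'
#' Re-scores ordinal/binary columns of a complete quantified matrix so that
#' the sum of squared pairwise Pearson correlations over all columns,
#' `J = sum_{i<j} cor(col_i, col_j)^2`, is maximised subject to each
#' variable's level-to-score map staying monotone non-decreasing.  The
#' algorithm is alternating least squares: cycling over ordinal variables,
#' each variable's candidate scores are the per-level means of the first
#' principal direction of all other (standardised) columns, made monotone by
#' weighted isotonic regression and standardised; a candidate is accepted
#' only if it does not decrease `J`, so the objective trace is non-decreasing
#' by construction.
#'
#' @param qm A complete `quantified_matrix` (impute first).
#' @param ordinal_columns Columns to re-score (indices or names); defaults to
#'   all ordinal/binary columns with a quantification map.
#' @param tol Convergence threshold on the change of `J` per sweep.
#' @param max_iter Maximum number of sweeps.
#' @return The re-scored `quantified_matrix`; attribute `"scaling_trace"`
#'   holds the `J` value before and after each sweep, and
#'   `"scaling_converged"` whether `|dJ| < tol` was reached.
#' @export
optimal_scaling <- function(qm, ordinal_columns = NULL, tol = 1e-6,
                            max_iter = 100L) {
  stopifnot(inherits(qm, "quantified_matrix"))
  M <- qm$values
  if (anyNA(M)) stopf("optimal scaling requires a complete matrix; impute first")
  if (is.null(ordinal_columns)) ordinal_columns <- names(qm$maps)
  if (is.character(ordinal_columns))
    ordinal_columns <- match(ordinal_columns, colnames(M))
  ordinal_columns <- ordinal_columns[!is.na(ordinal_columns)]

  # drop constant columns from the optimisation with a warning
  sds <- apply(M, 2, stats::sd)
  if (any(sds[ordinal_columns] == 0)) {
    warnf("excluding %d constant column(s) from optimal scaling",
          sum(sds[ordinal_columns] == 0))
    ordinal_columns <- ordinal_columns[sds[ordinal_columns] > 0]
  }
  active <- which(sds > 0)
  if (length(ordinal_columns) == 0L || length(active) < 2L) {
    attr(qm, "scaling_trace") <- scaling_objective(M[, active, drop = FALSE])
    attr(qm, "scaling_converged") <- TRUE
    return(qm)
  }

  Z <- apply(M[, active, drop = FALSE], 2, standardize_pop)
  colnames(Z) <- colnames(M)[active]
  # level index per row for each ordinal column (nearest quantified score)
  lev_idx <- list()
  for (j in ordinal_columns) {
    nm <- colnames(M)[j]
    map <- qm$maps[[nm]]
    lev_idx[[nm]] <- vapply(M[, j], function(v) which.min(abs(map$scores - v)),
                            integer(1))
  }

  J <- scaling_objective(Z)
  trace <- J
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    J_start <- J
    for (j in ordinal_columns) {
      nm <- colnames(M)[j]
      jz <- match(nm, colnames(Z))
      others <- Z[, -jz, drop = FALSE]
      if (!ncol(others)) next
      # target: projection of each row on the first principal direction of
      # the other columns
      v1 <- svd(others, nu = 0, nv = 1)$v[, 1]
      target <- drop(others %*% v1)
      idx <- lev_idx[[nm]]
      nl <- length(qm$maps[[nm]]$levels)
      w <- tabulate(idx, nl)
      meansl <- vapply(seq_len(nl), function(l)
        if (w[l] > 0) mean(target[idx == l]) else NA_real_, numeric(1))
      # empty levels interpolate between neighbours before isotonic fit
      if (anyNA(meansl))
        meansl <- stats::approx(which(!is.na(meansl)), meansl[!is.na(meansl)],
                                xout = seq_len(nl), rule = 2)$y
      iso <- pava(meansl, pmax(w, 1e-9))
      cand <- standardize_pop(iso[idx])
      if (is.null(cand)) next
      old <- Z[, jz]
      Z[, jz] <- cand
      J_new <- scaling_objective(Z)
      if (J_new >= J) {
        J <- J_new
        qm$maps[[nm]]$scores <- (iso - mean(iso[idx])) /
          sqrt(mean((iso[idx] - mean(iso[idx]))^2))
      } else {
        Z[, jz] <- old  # keep the previous scores: J must not decrease
      }
    }
    trace <- c(trace, J)
    if (abs(J - J_start) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warnf("optimal scaling did not converge in %d sweeps (dJ = %.3g)",
          max_iter, J - J_start)
  out <- qm
  out$values[, active] <- Z[, match(colnames(M)[active], colnames(Z))]
  attr(out, "scaling_trace") <- trace
  attr(out, "scaling_converged") <- converged
  out
}

#' Standardise all columns to z-scores
#'
#' Centres and scales every column to zero mean and unit variance using the
#' population (`1/N`) convention, matching the probability convention of the
#' latent-Gaussian quantification.  The constants are stored for the inverse
#' transform.
#'
#' @param qm A complete `quantified_matrix` (or bare numeric matrix).
#' @return The standardised `quantified_matrix` with `center` and `scale`
#'   filled in; zero-variance columns are set to 0 with a warning.
#' @export
zscore <- function(qm) {
  M <- qm_values(qm)
  if (anyNA(M)) stopf("zscore requires a complete matrix; impute first")
  mu <- colMeans(M)
  sd_ <- sqrt(colMeans(sweep(M, 2, mu)^2))
  if (any(sd_ == 0)) {
    warnf("%d zero-variance column(s) left at 0", sum(sd_ == 0))
  }
  scl <- ifelse(sd_ == 0, 1, sd_)
  Z <- sweep(sweep(M, 2, mu), 2, scl, "/")
  if (inherits(qm, "quantified_matrix")) {
    qm$values <- Z; qm$center <- mu; qm$scale <- scl
    qm
  } else {
    structure(list(values = Z, provenance = NULL, maps = list(),
                   center = mu, scale = scl),
              class = "quantified_matrix")
  }
}

#' PCA-based intrinsic dimension estimate
#'
#' Counts the eigenvalues of the covariance matrix that exceed the largest
#' eigenvalue divided by `C`: a scree-plot cutoff that serves as the default
#' SVD order for the imputers and as the `"auto"` reduction dimension.
#'
#' @param qm `quantified_matrix` or numeric matrix with >= 2 rows.
#' @param C Ratio cutoff (default 10).
#' @return Integer dimension estimate (>= 1).
#' @export
estimate_intrinsic_dimension_pca <- function(qm, C = 10) {
  M <- qm_values(qm)
  stopifnot(nrow(M) >= 2, C > 0)
  ev <- svd(sweep(M, 2, colMeans(M)), nu = 0, nv = 0)$d^2
  sum(ev > ev[1] / C)
}

#' PCA reduction of a quantified matrix
#'
#' @param qm Complete `quantified_matrix` or numeric matrix.
#' @param n_components Number of principal components (<= number of columns).
#' @return List with `scores` (n x n_components), `loadings`, `center`, and
#'   `explained` (per-component fractions of total variance, with
#'   `cumulative` attribute).
#' @export
reduce_dimension <- function(qm, n_components) {
  M <- qm_values(qm)
  if (anyNA(M)) stopf("reduce_dimension requires a complete matrix")
  if (!is_count(n_components) || n_components > ncol(M))
    stopf("n_components must be a count <= %d", ncol(M))
  ctr <- colMeans(M)
  Xc <- sweep(M, 2, ctr)
  sv <- svd(Xc, nu = n_components, nv = n_components)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  rownames(scores) <- rownames(M)
  colnames(scores) <- sprintf("PC%d", seq_len(n_components))
  expl <- sv$d^2 / sum(sv$d^2)
  out_expl <- expl[seq_len(n_components)]
  attr(out_expl, "cumulative") <- cumsum(expl)[seq_len(n_components)]
  list(scores = scores, loadings = sv$v, center = ctr, explained = out_expl)
}
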