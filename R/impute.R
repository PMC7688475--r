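#' @name impute
#' @title Low-rank SVD imputation of quantified matrices
#'
#' @description
#' Two multivariate imputers fill the missing cells of a quantified matrix
#' with points of a rank-`k` affine model of the data, avoiding the outliers
#' that univariate (per-column) imputation can create in a manifold-shaped
#' point cloud.
#'
#' * `svd_complete_impute()` ("SVDComplete") fits the rank-`k` PCA basis on
#'   the submatrix of fully observed rows only, then maps every incomplete
#'   row to the closest point of that affine hyperplane, closeness measured
#'   over the row's observed coordinates; the missing coordinates are read
#'   from the projected point.  It requires a reasonably large fraction of
#'   complete rows.
#' * `svd_full_impute()` ("SVDFull") iterates a rank-`k` approximation of
#'   the whole matrix: missing cells start at observed column means and are
#'   repeatedly overwritten by the low-rank reconstruction until the maximum
#'   absolute change falls below `tol`.  It only needs one observed value
#'   per column.
#'
#' With `round_discrete = TRUE`, imputed entries of ordinal/binary columns
#' are snapped to the nearest admissible quantified level, and dummy-coded
#' groups whose cells were all missing in a row are resolved to a single 1
#' at the largest imputed coordinate (mutual exclusivity).  Observed cells
#' are never modified by either imputer.
#'
#' The default order `k` is the PCA intrinsic-dimension estimate
#' ([estimate_intrinsic_dimension_pca()]) of the complete-row submatrix.
#'
#' @param qm A `quantified_matrix` whose `values` may contain `NA`.
#' @param k SVD order (default: intrinsic-dimension heuristic).
#' @param round_discrete Snap imputed ordinal/binary cells to admissible
#'   levels and enforce dummy-group exclusivity.
#' @param tol,max_iter Convergence control for `svd_full_impute`.
#' @return An object of class `imputation_result`: list with `qm` (the
#'   filled `quantified_matrix`), `imputed_cells` (2-column index matrix),
#'   `k`, `iterations`, `converged`, and for SVDFull an `objective_trace`
#'   of the observed-cell RMSE of the successive rank-`k` fits.
NULL

default_svd_order <- function(M) {
  complete <- which(stats::complete.cases(M))
  sub <- if (length(complete) >= 2) M[complete, , drop = FALSE] else NULL
  if (is.null(sub)) {
    mu <- colMeans(M, na.rm = TRUE)
    filled <- M
    for (j in seq_len(ncol(M))) filled[is.na(M[, j]), j] <- mu[j]
    sub <- filled
  }
  max(1L, estimate_intrinsic_dimension_pca(sub))
}

new_imputation_result <- function(qm, filled, imputed_cells, k, iterations,
                                  converged, trace = NULL) {
  qm$values <- filled
  structure(list(qm = qm, imputed_cells = imputed_cells, k = k,
                 iterations = iterations, converged = converged,
                 objective_trace = trace),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("<imputation_result> %d cells imputed (k = %d, %d iteration(s), %s)\n",
              nrow(x$imputed_cells), x$k, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @rdname impute
#' @export
svd_complete_impute <- function(qm, k = NULL, round_discrete = TRUE) {
  stopifnot(inherits(qm, "quantified_matrix"))
  M <- qm$values
  miss <- is.na(M)
  if (!any(miss))
    return(new_imputation_result(qm, M, cbind(row = integer(0), col = integer(0)),
                                 k %||% 0L, 0L, TRUE))
  complete <- which(stats::complete.cases(M))
  if (is.null(k)) k <- default_svd_order(M)
  if (length(complete) < k + 1)
    stopf(paste("only %d complete rows for SVD order k = %d;",
                "use svd_full_impute() instead"), length(complete), k)
  sub <- M[complete, , drop = FALSE]
  mu <- colMeans(sub)
  W <- svd(sweep(sub, 2, mu), nu = 0, nv = k)$v   # m x k orthonormal basis
  filled <- M
  for (i in which(rowSums(miss) > 0)) {
    obs <- which(!miss[i, ])
    if (length(obs) == 0) {
      filled[i, ] <- mu   # fully missing row: column means
      next
    }
    Wo <- W[obs, , drop = FALSE]
    t_ <- qr.coef(qr(Wo), M[i, obs] - mu[obs])
    t_[is.na(t_)] <- 0
    proj <- mu + drop(W %*% t_)
    filled[i, miss[i, ]] <- proj[miss[i, ]]
  }
  if (round_discrete) filled <- round_discrete_cells(filled, miss, qm)
  new_imputation_result(qm, filled, which(miss, arr.ind = TRUE), k, 1L, TRUE)
}

#' @rdname impute
#' @export
svd_full_impute <- function(qm, k = NULL, tol = 1e-6, max_iter = 200L,
                            round_discrete = TRUE) {
  stopifnot(inherits(qm, "quantified_matrix"))
  M <- qm$values
  miss <- is.na(M)
  if (!any(miss))
    return(new_imputation_result(qm, M, cbind(row = integer(0), col = integer(0)),
                                 k %||% 0L, 0L, TRUE))
  if (any(colSums(!miss) == 0))
    stopf("column(s) with no observed values: %s",
          paste(colnames(M)[colSums(!miss) == 0], collapse = ", "))
  if (is.null(k)) k <- default_svd_order(M)
  mu0 <- colMeans(M, na.rm = TRUE)
  filled <- M
  for (j in seq_len(ncol(M))) filled[miss[, j], j] <- mu0[j]
  converged <- FALSE
  trace <- numeric(0)
  it <- 0L
  for (it in seq_len(max_iter)) {
    mu <- colMeans(filled)
    Xc <- sweep(filled, 2, mu)
    sv <- svd(Xc, nu = k, nv = k)
    recon <- sweep(sv$u %*% (diag(sv$d[seq_len(k)], k) %*% t(sv$v)), 2, mu, "+")
    trace <- c(trace, sqrt(mean((recon[!miss] - M[!miss])^2)))
    delta <- max(abs(recon[miss] - filled[miss]))
    filled[miss] <- recon[miss]
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warnf("svd_full_impute: not converged after %d iterations", max_iter)
  if (round_discrete) filled <- round_discrete_cells(filled, miss, qm)
  new_imputation_result(qm, filled, which(miss, arr.ind = TRUE), k, it,
                        converged, trace)
}

# snap imputed ordinal/binary cells to the nearest quantified level and
# resolve all-missing dummy groups to a one-hot argmax
round_discrete_cells <- function(filled, miss, qm) {
  prov <- qm$provenance
  if (!is.null(prov)) {
    for (nm in names(qm$maps)) {
      j <- match(nm, colnames(filled))
      if (is.na(j) || !any(miss[, j])) next
      sc <- qm$maps[[nm]]$scores
      rows <- which(miss[, j])
      filled[rows, j] <- sc[vapply(filled[rows, j],
                                   function(v) which.min(abs(sc - v)),
                                   integer(1))]
    }
    dummies <- prov[prov$kind == "dummy", , drop = FALSE]
    for (src in unique(dummies$source)) {
      jj <- match(dummies$column[dummies$source == src], colnames(filled))
      allmiss <- rowSums(!miss[, jj, drop = FALSE]) == 0
      for (i in which(allmiss)) {
        v <- numeric(length(jj))
        v[which.max(filled[i, jj])] <- 1
        filled[i, jj] <- v
      }
      partial <- which(!allmiss & rowSums(miss[, jj, drop = FALSE]) > 0)
      for (i in partial) {
        m_j <- jj[miss[i, jj]]
        # an observed 1 forces imputed group mates to 0
        if (any(filled[i, jj[!miss[i, jj]]] == 1)) filled[i, m_j] <- 0
        else filled[i, m_j] <- as.numeric(filled[i, m_j] >= 0.5)
      }
    }
  }
  filled
}
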