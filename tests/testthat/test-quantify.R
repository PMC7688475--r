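test_that("latent-Gaussian scores match the normal-quantile oracle", {
  expect_equal(quantify_ordinal_univariate(c(5, 5)),
               qnorm(c(0.25, 0.75)), tolerance = 1e-12)
  expect_equal(round(quantify_ordinal_univariate(c(5, 5)), 4),
               c(-0.6745, 0.6745))
  expect_equal(quantify_ordinal_univariate(7), 0)
  expect_equal(quantify_ordinal_univariate(c(1, 2, 1)),
               qnorm(c(0.125, 0.5, 0.875)), tolerance = 1e-12)
  expect_equal(round(quantify_ordinal_univariate(c(1, 2, 1)), 4),
               c(-1.1503, 0, 1.1503))
  expect_error(quantify_ordinal_univariate(c(0, 0)), "all level counts")
})

test_that("scores are strictly increasing over positive-count levels and
           zero-count levels sit at their cumulative position", {
  set.seed(11)
  for (r in 1:50) {
    counts <- rpois(sample(2:8, 1), lambda = 5)
    if (sum(counts) == 0) counts[1] <- 1
    x <- quantify_ordinal_univariate(counts)
    pos <- which(counts > 0)
    expect_true(all(diff(x[pos]) > 0))
    # independent oracle, recomputed from first principles
    p <- counts / sum(counts)
    expect_equal(x, qnorm(cumsum(c(0, p))[seq_along(p)] + p / 2),
                 tolerance = 1e-10)
  }
})

test_that("dummy encoding partitions rows and propagates missingness", {
  v <- c("a", "b", "c", NA, "b")
  dm <- dummy_encode(v, c("a", "b", "c"))
  expect_equal(dim(dm), c(5L, 3L))
  expect_equal(unname(rowSums(dm)[c(1:3, 5)]), rep(1, 4))
  expect_true(all(is.na(dm[4, ])))
  dm2 <- dummy_encode(v, c("a", "b", "c"), drop_first = TRUE)
  expect_equal(colnames(dm2), c("b", "c"))
  expect_error(dummy_encode(v, "a"), ">= 2 levels")
  # a 7-cause outcome field yields 7 binary features
  causes <- as.character(1:7)
  dm7 <- dummy_encode(sample(causes, 30, replace = TRUE), causes)
  expect_equal(ncol(dm7), 7L)
})

test_that("quantify_dataset assembles scores, dummies and continuous columns", {
  df <- data.frame(sev = c("0", "0", "1", "2"),
                   cat = c("x", "y", "z", "x"),
                   age = c(50, 60, 55, 70))
  meta <- list(variable_meta("sev", "ordinal", c("0", "1", "2")),
               variable_meta("cat", "categorical", c("x", "y", "z")),
               variable_meta("age", "continuous"))
  qm <- quantify_dataset(mixed_dataset(df, meta))
  expect_equal(colnames(qm$values),
               c("sev", "cat=x", "cat=y", "cat=z", "age"))
  expect_equal(unname(qm$values[, "sev"]),
               qnorm(c(0.25, 0.25, 0.625, 0.875)), tolerance = 1e-10)
  expect_equal(qm$maps$sev$counts, c(2, 1, 1))
  expect_equal(unname(rowSums(qm$values[, 2:4])), rep(1, 4))
})

test_that("optimal scaling maximises pairwise correlation of monotone pairs", {
  set.seed(5)
  z <- rnorm(300)
  # two ordinal views of the same latent variable, different binnings
  a <- cut(z, c(-Inf, -0.5, 0.5, Inf), labels = c("0", "1", "2"))
  b <- cut(z, c(-Inf, -1, 0, 1, Inf), labels = c("0", "1", "2", "3"))
  df <- data.frame(a = as.character(a), b = as.character(b))
  meta <- list(variable_meta("a", "ordinal", c("0", "1", "2")),
               variable_meta("b", "ordinal", c("0", "1", "2", "3")))
  qm <- quantify_dataset(mixed_dataset(df, meta))
  sc <- optimal_scaling(qm)
  trace <- attr(sc, "scaling_trace")
  expect_true(all(diff(trace) >= -1e-12))          # monotone objective
  # identical permutations of levels reach corr^2 = 1
  df2 <- data.frame(a = c("0", "1", "2", "0", "1", "2"),
                    b = c("0", "1", "2", "0", "1", "2"))
  qm2 <- quantify_dataset(mixed_dataset(df2, list(
    variable_meta("a", "ordinal", c("0", "1", "2")),
    variable_meta("b", "ordinal", c("0", "1", "2")))))
  sc2 <- optimal_scaling(qm2)
  expect_equal(cor(sc2$values[, 1], sc2$values[, 2])^2, 1, tolerance = 1e-9)
})

test_that("a single ordinal column with nothing to optimise against keeps its
           univariate scores up to affine transform", {
  df <- data.frame(a = c("0", "0", "1", "2", "2", "2"))
  qm <- quantify_dataset(mixed_dataset(df, list(
    variable_meta("a", "ordinal", c("0", "1", "2")))))
  sc <- optimal_scaling(qm)
  expect_equal(cor(sc$values[, 1], qm$values[, 1]), 1, tolerance = 1e-9)
})

test_that("rescoring binned views of one latent Gaussian does not decrease J
           and keeps level maps monotone", {
  set.seed(9)
  z <- rnorm(400)
  mk <- function(br) as.character(cut(z, c(-Inf, br, Inf),
                                      labels = as.character(0:length(br))))
  df <- data.frame(a = mk(c(-1, 0.3)), b = mk(c(-0.2, 0.8)),
                   c = mk(c(-0.8, 0, 0.9)))
  meta <- list(variable_meta("a", "ordinal", c("0", "1", "2")),
               variable_meta("b", "ordinal", c("0", "1", "2")),
               variable_meta("c", "ordinal", c("0", "1", "2", "3")))
  qm <- quantify_dataset(mixed_dataset(df, meta))
  J_before <- sum(cor(qm$values)[upper.tri(diag(3))]^2)
  sc <- optimal_scaling(qm)
  J_after <- sum(cor(sc$values)[upper.tri(diag(3))]^2)
  expect_gte(J_after, J_before - 1e-12)
  for (map in sc$maps) expect_true(all(diff(map$scores) >= -1e-12))
})

test_that("z-scoring uses the population convention and stores constants", {
  qm <- qm_wrap(cbind(x = c(1, 2, 3), y = c(0, 1, 0)))
  z <- zscore(qm)
  expect_equal(unname(z$values[, "x"]),
               c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(unname(colMeans(z$values)), c(0, 0))
  expect_equal(unname(colMeans(z$values^2)), c(1, 1))
  # already standardized column is unchanged
  z2 <- zscore(qm_wrap(z$values))
  expect_equal(z2$values, z$values)
  # constant column: zeros plus warning
  expect_warning(zc <- zscore(qm_wrap(cbind(k = rep(4, 5)))), "zero-variance")
  expect_equal(unname(zc$values[, 1]), rep(0, 5))
  expect_equal(unname(zc$center["k"]), 4)
})

test_that("intrinsic dimension counts eigenvalues above the scree cutoff", {
  # data with exact covariance spectrum (10, 5, 0.5): threshold 1.0 at C=10
  set.seed(21)
  n <- 400
  Q <- qr.Q(qr(matrix(rnorm(n * 3), n, 3)))
  Q <- sweep(Q, 2, colMeans(Q))
  Q <- sweep(Q, 2, sqrt(colSums(Q^2)), "/")
  X <- Q %*% diag(sqrt(n * c(10, 5, 0.5)))
  ev <- eigen(crossprod(sweep(X, 2, colMeans(X))) / n)$values
  expect_equal(ev, c(10, 5, 0.5), tolerance = 1e-3)
  expect_equal(estimate_intrinsic_dimension_pca(X, C = 10), 2L)
  # exactly rank-1 data
  u <- rnorm(50)
  expect_equal(estimate_intrinsic_dimension_pca(cbind(u, 2 * u, -u)), 1L)
  # isotropic d-dimensional Gaussian recovers d
  G <- matrix(rnorm(2000 * 4), 2000, 4)
  expect_equal(estimate_intrinsic_dimension_pca(G, C = 10), 4L)
})

test_that("PCA reduction reports exact variance fractions", {
  # collinear 2-D data: one component explains everything
  t <- seq(-1, 1, length.out = 20)
  red <- reduce_dimension(cbind(t, 2 * t), 1)
  expect_equal(unname(red$explained[1]), 1.0)
  # orthogonal variances 4 and 1: first fraction 0.8
  set.seed(3)
  n <- 2000
  A <- cbind(rnorm(n, sd = 2), rnorm(n, sd = 1))
  red2 <- reduce_dimension(A, 1)
  expect_equal(unname(red2$explained[1]), 0.8, tolerance = 0.02)
  expect_error(reduce_dimension(A, 3), "n_components")
})

test_that("reduction fractions match an independent eigen-decomposition and
           attain the minimal rank-n reconstruction error", {
  set.seed(31)
  X <- matrix(rnorm(1000), 100, 10)
  red <- reduce_dimension(X, 4)
  ev <- eigen(stats::cov(sweep(X, 2, colMeans(X))), symmetric = TRUE)$values
  expect_equal(as.vector(red$explained), (ev / sum(ev))[1:4],
               tolerance = 1e-10)
  # Eckart-Young: reconstruction from scores/loadings matches truncated SVD
  recon <- sweep(red$scores %*% t(red$loadings), 2, red$center, "+")
  sv <- svd(sweep(X, 2, colMeans(X)))
  best <- sv$u[, 1:4] %*% diag(sv$d[1:4]) %*% t(sv$v[, 1:4])
  expect_equal(sum((X - recon)^2),
               sum((sweep(X, 2, colMeans(X)) - best)^2), tolerance = 1e-8)
})
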