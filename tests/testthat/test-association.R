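test_that("chi-squared deviation scores follow the independence arithmetic", {
  # perfectly independent 2x2 table: statistic 0, all deviations 0
  seg <- rep(c(1, 2), each = 20)
  var <- rep(c("a", "b"), 20)
  res <- segment_chi2(seg, var)
  expect_equal(res$statistic, 0)
  expect_true(all(abs(res$deviation) < 1e-12))

  # margins 40/40 and 40/40 with O = [[10,30],[30,10]]: E = 20 everywhere,
  # deviation (E-O)/E = +0.5 where O = 10 and -0.5 where O = 30
  seg2 <- rep(c(1, 2), each = 40)
  var2 <- c(rep("a", 10), rep("b", 30), rep("a", 30), rep("b", 10))
  res2 <- segment_chi2(seg2, var2)
  expect_equal(unname(res2$expected["1", "a"]), 20)
  expect_equal(unname(res2$deviation["1", "a"]), 0.5)
  expect_equal(unname(res2$deviation["1", "b"]), -0.5)
  expect_equal(unname(res2$deviation["2", "a"]), -0.5)

  # planted segment-specific class has the extreme |deviation|
  set.seed(41)
  seg3 <- sample(1:4, 400, replace = TRUE)
  var3 <- sample(c("x", "y"), 400, replace = TRUE)
  var3[seg3 == 3] <- "y"
  res3 <- segment_chi2(seg3, var3)
  dev <- res3$deviation
  expect_equal(unname(which(abs(dev) == max(abs(dev)), arr.ind = TRUE)[1, ]),
               c(3L, 1L))   # "x" depleted in segment 3
  expect_lt(res3$p, 1e-6)
})

test_that("segment ANOVA reports per-segment effects against the largest
           segment", {
  # identical group means: F ~ 0 coefficients ~ 0
  set.seed(43)
  seg <- rep(1:3, each = 50)
  y <- rnorm(150)
  res <- segment_anova(seg, y)
  expect_lt(res$statistic, 3)
  # two groups, means 0 and 1, sigma -> 0: coefficient 1
  seg2 <- rep(c(1, 2), c(60, 40))
  y2 <- c(rnorm(60, 0, 1e-8), rnorm(40, 1, 1e-8))
  res2 <- segment_anova(seg2, y2)
  expect_equal(res2$reference, "1")   # largest segment is the reference
  expect_equal(res2$effects$coefficient[res2$effects$segment == "2"], 1,
               tolerance = 1e-6)
  # planted shift on one of 5 segments dominates the coefficients
  seg3 <- rep(1:5, each = 40)
  y3 <- rnorm(200) + ifelse(seg3 == 4, 2, 0)
  res3 <- segment_anova(seg3, y3)
  eff <- res3$effects
  expect_equal(eff$segment[which.max(abs(eff$coefficient))], "4")
  # constant variable is flagged
  resc <- segment_anova(seg3, rep(1, 200))
  expect_true(resc$flagged)
  expect_true(is.na(resc$statistic))
})

test_that("kernel regression R2 tracks signal strength and is affine
           invariant", {
  set.seed(44)
  pt <- runif(120, 0, 3)
  # variable equal to pseudo-time: near-perfect fit
  ta <- trajectory_regression(pt, pt, kind = "continuous", bandwidth = 0.2)
  expect_gte(ta$r2, 0.99)
  expect_equal(ta$kind, "kernel")
  # independent noise: near-zero fit
  tn <- trajectory_regression(rnorm(120), pt, kind = "continuous",
                              bandwidth = 0.25)
  expect_lt(tn$r2, 0.05)
  # affine transform of the variable leaves R2 unchanged
  y <- sin(pt) + rnorm(120, sd = 0.2)
  r_a <- trajectory_regression(y, pt, kind = "continuous")$r2
  r_b <- trajectory_regression(5 - 3 * y, pt, kind = "continuous")$r2
  expect_equal(r_a, r_b, tolerance = 1e-12)
  # constant variable: R2 = 0
  expect_equal(trajectory_regression(rep(2, 50), runif(50),
                                     kind = "continuous")$r2, 0)
  expect_error(trajectory_regression(1:5, 1:5, kind = "continuous"),
               ">= 10 observations")
})

test_that("logistic trajectory regression locates a step at the midpoint", {
  set.seed(45)
  pt <- runif(400, 0, 4)
  y <- as.integer(pt > 2)
  flip <- runif(400) < 0.05          # 5% label noise avoids separation
  y[flip] <- 1L - y[flip]
  ta <- trajectory_regression(y, pt, kind = "binary")
  expect_equal(ta$kind, "logistic")
  cross <- ta$curve$pt[which.min(abs(ta$curve$fit - 0.5))]
  expect_lt(abs(cross - 2), 0.2)
  expect_gt(ta$r2, 0.5)
  # pure separation falls back to the ridge fit and flags it
  ysep <- as.integer(pt > 2)
  tsep <- trajectory_regression(ysep, pt, kind = "binary")
  expect_true(tsep$flagged)
  expect_true(is.finite(tsep$r2))
})

test_that("screening keeps exactly the planted association and honours
           thresholds", {
  gen <- generate_branching_dataset(
    tree_spec_star(3, arm_lengths = 1, m = 4, sigma = 0.05,
                   n_per_branch = 80), seed = 47)
  fit <- grow_tree(gen$X, n_nodes = 18, seed = 47)
  G <- extend_leaves(fit$graph, gen$X)
  root <- partition_points(gen$node_positions[1, , drop = FALSE], G)$assignment
  pt <- compute_pseudotime(gen$X, G, root = root)
  n <- nrow(gen$X)
  set.seed(48)
  df <- data.frame(noise1 = rnorm(n),
                   noise2 = sample(c("0", "1"), n, replace = TRUE),
                   signal = gen$truth$pseudotime + rnorm(n, sd = 0.05))
  meta <- list(variable_meta("noise1", "continuous"),
               variable_meta("noise2", "binary", c("0", "1")),
               variable_meta("signal", "continuous"))
  ds <- mixed_dataset(df, meta, row_ids = pt$row_id)

  sc <- screen_associations(ds, pt)
  kept <- sc$trajectory_table[sc$trajectory_table$kept, ]
  expect_true(all(kept$variable == "signal"))
  expect_gt(nrow(kept), 0)
  # pure-noise variables never pass the default R2 threshold
  noise_rows <- sc$trajectory_table$variable != "signal"
  expect_true(all(!sc$trajectory_table$kept[noise_rows]))
  # threshold 0 retains every tested pair
  sc0 <- screen_associations(ds, pt, r2_threshold = 0)
  expect_true(all(sc0$trajectory_table$kept))
  # an all-noise dataset yields an empty result at default thresholds
  ds_noise <- mixed_dataset(df[, 1:2], meta[1:2], row_ids = pt$row_id)
  scn <- screen_associations(ds_noise, pt)
  expect_equal(sum(scn$trajectory_table$kept), 0L)
  expect_equal(sum(scn$segment_table$kept), 0L)
})
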