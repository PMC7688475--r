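#' Chi-squared association between segments and a categorical variable
#'
#' Tests independence of the segment labelling and a categorical (or binary)
#' variable, and scores each (segment, level) cell by the deviation
#' `(E - O) / E` between expected and observed counts under independence:
#' positive deviations mark positive enrichment, negative deviations
#' depletion.  Missing variable entries are excluded pairwise.
#'
#' @param segment_labels Integer/factor segment id per observation.
#' @param var Categorical values per observation (`NA` allowed).
#' @param variable Name used in reports.
#' @return An object of class `segment_association` with the test statistic,
#'   p-value, and the deviation, observed and expected matrices
#'   (segments x levels); cells with zero expected count have `NA` deviation
#'   and set the `flagged` field.
#' @export
segment_chi2 <- function(segment_labels, var, variable = "variable") {
  ok <- !is.na(var) & !is.na(segment_labels)
  tab <- table(segment = segment_labels[ok], level = var[ok])
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stopf("chi-squared needs >= 2 segments and >= 2 observed levels")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  E <- ct$expected
  dev <- (E - tab) / E
  flagged <- any(E == 0)
  dev[E == 0] <- NA
  structure(list(variable = variable, test = "chi2",
                 statistic = unname(ct$statistic), p = ct$p.value,
                 p_adj = NA_real_, deviation = as.matrix(dev),
                 observed = as.matrix(tab), expected = as.matrix(E),
                 flagged = flagged),
            class = "segment_association")
}

#' ANOVA association between segments and a numeric variable
#'
#' One-way ANOVA of the variable on the segment labelling (one-hot coded
#' with the largest segment as reference).  Each non-reference segment's
#' effect is its coefficient (segment mean minus reference mean) with its
#' linear-model p-value.
#'
#' @param segment_labels Segment id per observation.
#' @param var Numeric values (`NA` allowed).
#' @param variable Name used in reports.
#' @return An object of class `segment_association` with the F statistic,
#'   its p-value, and a per-segment `effects` data.frame; a constant
#'   variable yields `NA` statistic and `flagged = TRUE`.
#' @export
segment_anova <- function(segment_labels, var, variable = "variable") {
  ok <- !is.na(var) & !is.na(segment_labels)
  seg <- factor(segment_labels[ok])
  y <- as.numeric(var[ok])
  if (nlevels(seg) < 2) stopf("ANOVA needs >= 2 segments")
  ref <- names(which.max(table(seg)))
  seg <- stats::relevel(seg, ref = ref)
  if (stats::sd(y) == 0 || any(table(seg) < 2)) {
    return(structure(list(variable = variable, test = "anova",
                          statistic = NA_real_, p = NA_real_,
                          p_adj = NA_real_, effects = NULL, flagged = TRUE),
                     class = "segment_association"))
  }
  fit <- stats::lm(y ~ seg)
  fs <- summary(fit)$fstatistic
  p <- stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)
  cf <- summary(fit)$coefficients[-1, , drop = FALSE]
  effects <- data.frame(segment = sub("^seg", "", rownames(cf)),
                        coefficient = cf[, "Estimate"],
                        p = cf[, "Pr(>|t|)"], row.names = NULL)
  structure(list(variable = variable, test = "anova",
                 statistic = unname(fs[1]), p = unname(p),
                 p_adj = NA_real_, effects = effects,
                 reference = ref, flagged = FALSE),
            class = "segment_association")
}

#' @export
print.segment_association <- function(x, ...) {
  cat(sprintf("<segment_association> %s: %s = %.4g, p = %.3g%s\n",
              x$variable, if (x$test == "chi2") "chi2" else "F",
              x$statistic, x$p, if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

# Nadaraya-Watson regression with a Gaussian kernel
nw_fit <- function(pt, y, at, bandwidth) {
  K <- exp(-outer(at, pt, "-")^2 / (2 * bandwidth^2))
  drop(K %*% y) / pmax(rowSums(K), .Machine$double.xmin)
}

# logistic regression of y on pt with a small ridge fallback on separation
logistic_fit <- function(pt, y, ridge = 1e-4) {
  flagged <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ pt, family = stats::binomial()),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  if (flagged || any(!is.finite(beta)) || max(abs(beta)) > 1e3) {
    # ridge-penalised IRLS keeps the fit finite under separation
    flagged <- TRUE
    Xm <- cbind(1, pt)
    beta <- c(0, 0)
    for (it in 1:50) {
      eta <- drop(Xm %*% beta)
      p_ <- 1 / (1 + exp(-eta))
      W <- pmax(p_ * (1 - p_), 1e-10)
      z <- eta + (y - p_) / W
      A <- crossprod(Xm, W * Xm) + diag(ridge, 2)
      bnew <- solve(A, crossprod(Xm, W * z))
      if (max(abs(bnew - beta)) < 1e-8) { beta <- drop(bnew); break }
      beta <- drop(bnew)
    }
  }
  list(beta = beta, flagged = flagged,
       predict = function(at) 1 / (1 + exp(-(beta[1] + beta[2] * at))))
}

#' Regression of a variable on pseudo-time along one trajectory
#'
#' Continuous and ordinal variables are fitted by Gaussian-kernel
#' (Nadaraya-Watson) regression of the value on pseudo-time, with
#' `R2 = 1 - SSres / SStot`.  Binary variables are fitted by logistic
#' regression of the outcome on pseudo-time, with `R2` the squared Pearson
#' correlation between the fitted probability and the outcome (a design
#' choice; separation triggers a small-ridge refit and a flag).  The fitted
#' curve is returned on a uniform pseudo-time grid.
#'
#' @param values Variable values on the trajectory's observations.
#' @param pt Pseudo-time values (same length, >= 10 observations).
#' @param kind `"continuous"`, `"ordinal"` or `"binary"`.
#' @param bandwidth Gaussian kernel bandwidth in pseudo-time units
#'   (default 0.25 edge units).
#' @param grid_n Number of grid points for the fitted curve.
#' @param variable,trajectory Names used in reports.
#' @return An object of class `trajectory_association` with `r2`, the
#'   regression `kind` (`"kernel"` or `"logistic"`), the `curve`
#'   (data.frame `pt`, `fit`) and a `flagged` field.
#' @export
trajectory_regression <- function(values, pt,
                                  kind = c("continuous", "ordinal", "binary"),
                                  bandwidth = 0.25, grid_n = 50L,
                                  variable = "variable", trajectory = NA) {
  kind <- match.arg(kind)
  ok <- !is.na(values) & !is.na(pt)
  values <- values[ok]; pt <- pt[ok]
  if (length(pt) < 10) stopf("need >= 10 observations on the trajectory")
  grid <- seq(min(pt), max(pt), length.out = grid_n)
  flagged <- FALSE
  if (kind == "binary") {
    y <- as.numeric(factor(values)) - 1
    if (length(unique(y)) < 2) {
      r2 <- 0
      curve <- data.frame(pt = grid, fit = mean(y))
      reg_kind <- "logistic"
    } else {
      lf <- logistic_fit(pt, y)
      flagged <- lf$flagged
      fitted <- lf$predict(pt)
      r2 <- if (stats::sd(fitted) == 0) 0 else stats::cor(fitted, y)^2
      curve <- data.frame(pt = grid, fit = lf$predict(grid))
      reg_kind <- "logistic"
    }
  } else {
    y <- as.numeric(values)
    if (stats::sd(y) == 0) {
      r2 <- 0
      curve <- data.frame(pt = grid, fit = mean(y))
    } else {
      fitted <- nw_fit(pt, y, pt, bandwidth)
      r2 <- max(0, 1 - sum((y - fitted)^2) / sum((y - mean(y))^2))
      curve <- data.frame(pt = grid, fit = nw_fit(pt, y, grid, bandwidth))
    }
    reg_kind <- "kernel"
  }
  structure(list(variable = variable, trajectory = trajectory, r2 = r2,
                 kind = reg_kind, curve = curve, n = length(pt),
                 flagged = flagged),
            class = "trajectory_association")
}

#' @export
print.trajectory_association <- function(x, ...) {
  cat(sprintf("<trajectory_association> %s ~ Pt (trajectory %s): %s R2 = %.3f%s\n",
              x$variable, x$trajectory, x$kind, x$r2,
              if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

# numeric view of a variable for ANOVA / kernel regression: ordinal levels
# map to their rank, binary to 0/1
variable_numeric <- function(v, m) {
  if (m$kind == "continuous") as.numeric(v)
  else as.numeric(match(v, m$levels)) - 1
}

#' Screen all variables against segments and trajectories
#'
#' Runs [segment_chi2()] / [segment_anova()] for every variable against the
#' segment partition, and [trajectory_regression()] for every
#' (variable, trajectory) pair, then keeps
#' * variable-trajectory pairs with `R2 > r2_threshold`, and
#' * variable-segment effects from tests significant after
#'   Benjamini-Hochberg adjustment (level `fdr`) with absolute effect
#'   (deviation score or ANOVA coefficient) above `effect_threshold`.
#'
#' Binary and categorical variables are tested by chi-squared with deviation
#' scores; ordinal and continuous variables by ANOVA (ordinal levels enter
#' as ranks).
#'
#' @param ds A [mixed_dataset()] holding the variables to screen.
#' @param pt A [compute_pseudotime()] table for the same observations.
#' @param variables Which variables to screen (default: all in `ds`).
#' @param r2_threshold Minimum trajectory regression `R2` (default 0.3).
#' @param effect_threshold Minimum absolute deviation / coefficient.
#' @param fdr Benjamini-Hochberg level across variables per analysis.
#' @param bandwidth Kernel bandwidth for [trajectory_regression()].
#' @param min_n Minimum observations on a trajectory to attempt regression.
#' @return List of class `association_screen` with long-format data.frames
#'   `trajectory_table` (variable, trajectory, kind, r2, n, kept) and
#'   `segment_table` (variable, test, statistic, p, p_adj, segment, level,
#'   effect, kept).
#' @export
screen_associations <- function(ds, pt, variables = NULL,
                                r2_threshold = 0.3, effect_threshold = 0.3,
                                fdr = 0.05, bandwidth = 0.25, min_n = 10L) {
  stopifnot(inherits(ds, "mixed_dataset"), inherits(pt, "pseudotime_table"))
  if (is.null(variables)) variables <- names(ds$meta)
  idx <- match(pt$row_id, ds$row_ids)
  if (anyNA(idx)) stopf("pseudotime table rows not found in dataset")
  trajectories <- attr(pt, "trajectory_list")
  seg_labels <- pt$segment

  traj_rows <- list(); seg_rows <- list(); seg_tests <- list()
  for (nm in variables) {
    m <- ds$meta[[nm]]
    v <- ds$values[[nm]][idx]
    # segment tests
    res <- tryCatch({
      if (m$kind %in% c("binary", "categorical"))
        segment_chi2(seg_labels, v, variable = nm)
      else
        segment_anova(seg_labels, variable_numeric(v, m), variable = nm)
    }, error = function(e) NULL)
    if (!is.null(res)) seg_tests[[nm]] <- res
    # trajectory regressions
    for (tr in trajectories) {
      on_tr <- vapply(pt$trajectories, function(ids) tr$id %in% ids,
                      logical(1))
      use <- on_tr & !is.na(v)
      if (sum(use) < min_n) next
      ta <- trajectory_regression(
        v[use], pt$pseudotime[use],
        kind = if (m$kind %in% c("binary")) "binary"
               else if (m$kind == "continuous") "continuous" else "ordinal",
        bandwidth = bandwidth, variable = nm, trajectory = tr$id)
      traj_rows[[length(traj_rows) + 1L]] <-
        data.frame(variable = nm, trajectory = tr$id, kind = ta$kind,
                   r2 = ta$r2, n = ta$n, kept = ta$r2 > r2_threshold)
    }
  }
  # BH adjustment across variables, separately per test family
  for (fam in c("chi2", "anova")) {
    nms <- names(seg_tests)[vapply(seg_tests, function(x) x$test == fam,
                                   logical(1))]
    if (!length(nms)) next
    padj <- stats::p.adjust(vapply(seg_tests[nms], `[[`, numeric(1), "p"),
                            method = "BH")
    for (i in seq_along(nms)) seg_tests[[nms[i]]]$p_adj <- padj[i]
  }
  for (res in seg_tests) {
    if (res$test == "chi2") {
      dev <- res$deviation
      for (si in rownames(dev)) for (li in colnames(dev)) {
        eff <- dev[si, li]
        seg_rows[[length(seg_rows) + 1L]] <- data.frame(
          variable = res$variable, test = "chi2", statistic = res$statistic,
          p = res$p, p_adj = res$p_adj, segment = si, level = li,
          effect = eff,
          kept = isTRUE(res$p_adj < fdr && !is.na(eff) &&
                          abs(eff) > effect_threshold))
      }
    } else if (!is.null(res$effects)) {
      for (r in seq_len(nrow(res$effects))) {
        ef <- res$effects[r, ]
        seg_rows[[length(seg_rows) + 1L]] <- data.frame(
          variable = res$variable, test = "anova", statistic = res$statistic,
          p = res$p, p_adj = res$p_adj, segment = ef$segment,
          level = NA_character_, effect = ef$coefficient,
          kept = isTRUE(res$p_adj < fdr && ef$p < 0.05 &&
                          abs(ef$coefficient) > effect_threshold))
      }
    }
  }
  empty_traj <- data.frame(variable = character(0), trajectory = integer(0),
                           kind = character(0), r2 = numeric(0),
                           n = integer(0), kept = logical(0))
  empty_seg <- data.frame(variable = character(0), test = character(0),
                          statistic = numeric(0), p = numeric(0),
                          p_adj = numeric(0), segment = character(0),
                          level = character(0), effect = numeric(0),
                          kept = logical(0))
  structure(list(
    trajectory_table = if (length(traj_rows)) do.call(rbind, traj_rows)
                       else empty_traj,
    segment_table = if (length(seg_rows)) do.call(rbind, seg_rows)
                    else empty_seg,
    tests = seg_tests),
    class = "association_screen")
}

#' @export
print.association_screen <- function(x, ...) {
  cat(sprintf("<association_screen> %d/%d trajectory pairs kept, %d/%d segment effects kept\n",
              sum(x$trajectory_table$kept), nrow(x$trajectory_table),
              sum(x$segment_table$kept), nrow(x$segment_table)))
  invisible(x)
}
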