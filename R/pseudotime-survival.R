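#' Event table for pseudo-time survival analysis
#'
#' Container for survival analysis where pseudo-time along one trajectory
#' plays the role of time-on-study: each observation contributes its
#' pseudo-time and an event indicator (with optional cause label and
#' covariates); observations without an event are right-censored at their
#' pseudo-time.
#'
#' @param time Non-negative times (pseudo-times).
#' @param event 0/1 (or logical) event indicator.
#' @param cause Optional cause label per event (required for cause-specific
#'   analysis; ignored rows may be `NA` when `event == 0`).
#' @param covariates Optional numeric matrix/data.frame of covariates.
#' @param id Optional observation identifiers.
#' @return An object of class `event_table`.
#' @export
event_table <- function(time, event, cause = NULL, covariates = NULL,
                        id = NULL) {
  time <- as.numeric(time)
  event <- as.integer(as.logical(event))
  stopifnot(length(time) >= 1, length(event) == length(time),
            all(time >= 0), !anyNA(time))
  if (!is.null(cause)) {
    stopifnot(length(cause) == length(time))
    if (any(event == 1 & is.na(cause)))
      stopf("every event needs a defined cause for cause-specific analysis")
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(as.data.frame(covariates))
    stopifnot(nrow(covariates) == length(time))
  }
  structure(list(time = time, event = event, cause = cause,
                 covariates = covariates,
                 id = id %||% as.character(seq_along(time))),
            class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %d observations, %d events%s%s\n",
              length(x$time), sum(x$event),
              if (!is.null(x$cause))
                sprintf(", %d causes", length(unique(x$cause[x$event == 1])))
              else "",
              if (!is.null(x$covariates))
                sprintf(", %d covariates", ncol(x$covariates)) else ""))
  invisible(x)
}

#' Build the event table of a single trajectory
#'
#' Survival analysis over pseudo-time must be run per trajectory: pooling
#' observations of different trajectories into one risk set would mix
#' incomparable time scales, so this constructor accepts exactly one
#' trajectory id and subsets the pseudo-time table to the observations
#' lying on it.
#'
#' @param pt A [compute_pseudotime()] table.
#' @param trajectory A single trajectory id.
#' @param event Event indicator for all observations of `pt` (matched by
#'   position).
#' @param cause,covariates Optional, matched by position as well.
#' @return An [event_table()] restricted to the trajectory.
#' @export
trajectory_events <- function(pt, trajectory, event, cause = NULL,
                              covariates = NULL) {
  stopifnot(inherits(pt, "pseudotime_table"))
  if (length(trajectory) != 1L)
    stopf("survival analysis is per-trajectory: supply exactly one trajectory id")
  on_tr <- vapply(pt$trajectories, function(ids) trajectory %in% ids,
                  logical(1))
  if (!any(on_tr)) stopf("no observations on trajectory %s", trajectory)
  event_table(pt$pseudotime[on_tr], event[on_tr],
              cause = if (!is.null(cause)) cause[on_tr],
              covariates = if (!is.null(covariates))
                as.matrix(as.data.frame(covariates))[on_tr, , drop = FALSE],
              id = pt$row_id[on_tr])
}

#' Nelson-Aalen cumulative hazard over pseudo-time
#'
#' The non-parametric estimator `H(t) = sum over t_i <= t of d_i / n_i`,
#' with `d_i` events and `n_i` at risk at the distinct event time `t_i`.
#' The variance per step is `sum d_i / n_i^2` and confidence bands use the
#' log transform.
#'
#' @param events An [event_table()].
#' @param conf_level Confidence level for the bands.
#' @return A data.frame of class `hazard_curve` with columns `time`,
#'   `hazard`, `variance`, `lower`, `upper`, `n_risk`, `n_event`, one row
#'   per distinct event time (empty with `H == 0` if there are no events).
#' @export
nelson_aalen <- function(events, conf_level = 0.95) {
  stopifnot(inherits(events, "event_table"))
  if (sum(events$event) == 0) {
    out <- data.frame(time = numeric(0), hazard = numeric(0),
                      variance = numeric(0), lower = numeric(0),
                      upper = numeric(0), n_risk = integer(0),
                      n_event = integer(0))
    class(out) <- c("hazard_curve", "data.frame")
    return(out)
  }
  sf <- survival::survfit(survival::Surv(events$time, events$event) ~ 1)
  keep <- sf$n.event > 0
  d <- sf$n.event[keep]; n <- sf$n.risk[keep]
  H <- cumsum(d / n)
  v <- cumsum(d / n^2)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se_log <- sqrt(v) / H
  out <- data.frame(time = sf$time[keep], hazard = H, variance = v,
                    lower = H * exp(-z * se_log), upper = H * exp(z * se_log),
                    n_risk = n, n_event = d)
  class(out) <- c("hazard_curve", "data.frame")
  out
}

#' Evaluate a cumulative hazard curve at arbitrary times
#' @param curve A `hazard_curve`.
#' @param t Times.
#' @return `H(t)` as a step function (0 before the first event).
#' @export
hazard_at <- function(curve, t) {
  if (!nrow(curve)) return(rep(0, length(t)))
  idx <- findInterval(t, curve$time)
  c(0, curve$hazard)[idx + 1]
}

#' Cause-specific Nelson-Aalen hazards
#'
#' For every cause, the Nelson-Aalen estimator treating that cause as the
#' event and every other outcome as censoring.  Because all causes share
#' the same risk sets, the per-step increments of the cause-specific curves
#' sum to the all-cause increments.
#'
#' @param events An [event_table()] with cause labels.
#' @param causes Causes to analyse (default: all observed among events);
#'   an unknown label is an error.
#' @return Named list of `hazard_curve` objects.
#' @export
cause_specific_hazards <- function(events, causes = NULL) {
  stopifnot(inherits(events, "event_table"))
  if (is.null(events$cause)) stopf("event table has no cause labels")
  observed <- unique(events$cause[events$event == 1])
  if (is.null(causes)) causes <- sort(observed)
  unknown <- setdiff(causes, unique(events$cause[!is.na(events$cause)]))
  if (length(unknown))
    stopf("unknown cause label(s): %s", paste(unknown, collapse = ", "))
  out <- lapply(causes, function(cc) {
    ev <- events
    ev$event <- as.integer(events$event == 1 & events$cause == cc)
    nelson_aalen(ev)
  })
  names(out) <- causes
  out
}

#' Kaplan-Meier survival over pseudo-time, by group
#'
#' Product-limit estimator per group, evaluated on the union of all event
#' times so that group curves are directly comparable.
#'
#' @param events An [event_table()].
#' @param groups Group label per observation (default: one group).
#' @return Data.frame with columns `group`, `time`, `survival`, `n_risk`,
#'   `n_event`.
#' @export
kaplan_meier <- function(events, groups = NULL) {
  stopifnot(inherits(events, "event_table"))
  if (is.null(groups)) groups <- rep("all", length(events$time))
  stopifnot(length(groups) == length(events$time))
  if (any(table(factor(groups)) == 0) || anyNA(groups))
    stopf("every group needs >= 1 observation")
  times <- sort(unique(events$time[events$event == 1]))
  if (!length(times)) times <- max(events$time)
  out <- list()
  for (gl in sort(unique(as.character(groups)))) {
    sel <- groups == gl
    sf <- survival::survfit(
      survival::Surv(events$time[sel], events$event[sel]) ~ 1)
    sm <- summary(sf, times = times, extend = TRUE)
    out[[gl]] <- data.frame(group = gl, time = sm$time, survival = sm$surv,
                            n_risk = sm$n.risk, n_event = sm$n.event)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Cox proportional-hazards regression on pseudo-time
#'
#' Multivariate Cox regression of the pseudo-time-to-event on standardized
#' covariates, with Breslow handling of ties.  Collinear covariates
#' (singular information matrix) are an error; a monotone partial
#' likelihood (separation) triggers a ridge-stabilised refit and a flag.
#'
#' @param events An [event_table()] with covariates and >= 2 events.
#' @param ridge Ridge penalty used by the stabilised fallback.
#' @return An object of class `cox_fit`: data.frame `coefficients` with
#'   `term`, `coef`, `se`, `hr`, `lower`, `upper`, `p`; plus `loglik`,
#'   `converged` and `flagged`.
#' @export
cox_regression <- function(events, ridge = 0.1) {
  stopifnot(inherits(events, "event_table"))
  if (is.null(events$covariates)) stopf("event table has no covariates")
  if (sum(events$event) < 2) stopf("need >= 2 events")
  X <- events$covariates
  qrX <- qr(scale(X, scale = FALSE))
  if (qrX$rank < ncol(X))
    stopf("singular information matrix: collinear covariates (%s)",
          paste(colnames(X)[qrX$pivot[-seq_len(qrX$rank)]], collapse = ", "))
  dat <- data.frame(X, check.names = FALSE)
  dat$.time <- events$time; dat$.event <- events$event
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "breslow"),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (flagged || any(!is.finite(stats::coef(fit)))) {
    flagged <- TRUE
    rfml <- stats::as.formula(paste(
      "survival::Surv(.time, .event) ~ survival::ridge(",
      paste(sprintf("`%s`", colnames(X)), collapse = ", "),
      ", theta = ", ridge, ")"))
    fit <- suppressWarnings(
      survival::coxph(rfml, data = dat, ties = "breslow"))
  }
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- stats::qnorm(0.975)
  coefs <- data.frame(term = colnames(X), coef = unname(beta),
                      se = unname(se), hr = exp(unname(beta)),
                      lower = exp(unname(beta) - z * unname(se)),
                      upper = exp(unname(beta) + z * unname(se)),
                      p = 2 * stats::pnorm(-abs(unname(beta) / unname(se))),
                      row.names = NULL)
  structure(list(coefficients = coefs,
                 loglik = fit$loglik[length(fit$loglik)],
                 converged = is.null(fit$info) || fit$iter < fit$control$iter.max,
                 flagged = flagged),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> %d covariates, log partial likelihood %.3f%s\n",
              nrow(x$coefficients), x$loglik,
              if (x$flagged) " [ridge-stabilised]" else ""))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Top positive and negative Cox coefficients
#' @param fit A `cox_fit`.
#' @param k How many of each sign.
#' @return Data.frame of the `k` most positive and `k` most negative
#'   coefficients (hazard-increasing and hazard-decreasing covariates).
#' @export
cox_top_coefficients <- function(fit, k = 5L) {
  cf <- fit$coefficients[order(fit$coefficients$coef, decreasing = TRUE), ]
  pos <- utils::head(cf[cf$coef > 0, ], k)
  neg <- utils::tail(cf[cf$coef < 0, ], k)
  rbind(pos, neg)
}
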