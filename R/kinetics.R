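# Single-hit exponential kinetics: Kaplan-Meier estimation and extraction
# of the initiation half-time from the tail of the log-survival curve.

#' Kaplan-Meier tumor-free survival curve for one group
#'
#' Product-limit estimate of tumor-free survival with right-censoring,
#' computed with [survival::survfit()]. Simultaneous events share a step.
#'
#' @param table survival data frame with columns `time_weeks` and `event`
#'   (and optionally `group`).
#' @param group if given, restrict to rows with this `group` label.
#' @return an object of class `km_curve`: a list with the step times,
#'   survival values, numbers at risk/events, and Greenwood standard
#'   errors of `log S`.
#' @seealso [fit_single_hit()]
#' @export
km_estimate <- function(table, group = NULL) {
  if (!is.null(group)) {
    table <- table[table$group == group, , drop = FALSE]
    if (nrow(table) == 0L) {
      stop("no subjects in group '", group, "'", call. = FALSE)
    }
  }
  if (nrow(table) == 0L) stop("empty survival table", call. = FALSE)
  fit <- survival::survfit(
    survival::Surv(time_weeks, event) ~ 1,
    data = table, conf.type = "none"
  )
  structure(
    list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
         n_event = fit$n.event, n_censor = fit$n.censor,
         std_err_log = fit$std.err,   # SE of log S (Greenwood)
         n = sum(fit$n), group = group),
    class = "km_curve"
  )
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d subjects, %d events\n",
              x$n, sum(x$n_event)))
  invisible(x)
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param object a `km_curve`.
#' @param times times at which to evaluate the right-continuous step
#'   function (survival is 1 before the first observed time).
#' @param ... unused.
#' @return survival fractions at `times`.
#' @export
predict.km_curve <- function(object, times, ...) {
  stats::stepfun(object$time, c(1, object$surv), right = FALSE)(times)
}

#' Weighted log-linear fit of survival versus time
#'
#' The core of the tail fit: weighted least squares of `log(surv)` on
#' `time`; under single-hit kinetics `log S(t) = lambda * t0 - lambda * t`,
#' so the slope estimates `-lambda` regardless of the detection lag.
#'
#' @param time step times.
#' @param surv survival values (must be positive; zero-survival steps are
#'   excluded upstream).
#' @param weights observation weights (default equal).
#' @return list with `lambda`, `intercept`, `se_lambda` (residual-based),
#'   and the fitted `lm` object.
#' @export
fit_log_survival <- function(time, surv, weights = NULL) {
  stopifnot(length(time) == length(surv))
  if (any(surv <= 0)) stop("'surv' must be positive (log undefined at 0)",
                           call. = FALSE)
  if (length(unique(time)) < 3L) {
    stop("need at least 3 distinct times for the log-linear fit",
         call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, length(time))
  fit <- stats::lm(log(surv) ~ time, weights = weights)
  slope <- unname(stats::coef(fit)[2])
  lambda <- -slope
  if (!is.finite(lambda) || lambda <= 0) {
    stop("log-survival is non-decreasing over the fit window ",
         "(estimated rate <= 0); single-hit kinetics cannot be fit. ",
         "Check the tail window and that events are present.",
         call. = FALSE)
  }
  list(lambda = lambda,
       intercept = unname(stats::coef(fit)[1]),
       se_lambda = unname(sqrt(diag(stats::vcov(fit)))[2]),
       fit = fit)
}

# Variance of the WLS slope propagated through the independent-increments
# (Greenwood) covariance of log S: Cov(log S_j, log S_l) = G_{min(j,l)}
# with G_j the cumulative sum of d/(n(n-d)) over event steps up to j.
greenwood_slope_var <- function(time, weights, greenwood_cum) {
  w <- weights / sum(weights)
  tbar <- sum(w * time)
  sxx <- sum(weights * (time - tbar)^2)
  a <- weights * (time - tbar) / sxx      # slope = sum(a * y)
  jmin <- outer(seq_along(time), seq_along(time), pmin)
  vmat <- matrix(greenwood_cum[jmin], nrow = length(time))
  drop(t(a) %*% vmat %*% a)
}

#' Fit the single-hit initiation model to censored tumor-free survival
#'
#' Under single-hit kinetics, tumors initiate with a constant probability
#' per unit time, so tumor-free survival declines as a single exponential
#' `S(t) = exp(-lambda * (t - t0))` beyond the detection lag `t0`. The
#' half-time `t_1/2 = log(2) / lambda` is the expected time (past the lag)
#' for tumors to arise in half the cohort.
#'
#' Two estimators are provided:
#' \describe{
#'   \item{`"log-linear-tail"` (default)}{Weighted least squares of the
#'     log Kaplan-Meier survival against time over the tail window, with
#'     weights equal to the number at risk at each step; the slope is
#'     `-lambda`. The slope variance is propagated through the Greenwood
#'     independent-increments covariance of `log S` rather than taken from
#'     the regression residuals, which are serially correlated. The
#'     default window starts at the first observed event (the lag region
#'     carries no information about the initiation rate) and zero-survival
#'     steps are excluded.}
#'   \item{`"shifted-exp-mle"`}{Censored maximum likelihood for
#'     `time = t0 + Exponential(lambda)`: `lambda = events / total time at
#'     risk past t0`, with `t0` fixed (via `lag_weeks`) or profiled on a
#'     0.5-week grid up to the first event time. The profile likelihood is
#'     maximized at the boundary (the largest admissible `t0`), the usual
#'     degeneracy of the shifted exponential.}
#' }
#'
#' @param table survival data frame (`time_weeks`, `event`, optionally
#'   `group`).
#' @param group optional group label to restrict to.
#' @param tail_window numeric length-2 `(t_start, t_end)`; default from the
#'   first observed event to the last observed time.
#' @param method `"log-linear-tail"` or `"shifted-exp-mle"`.
#' @param lag_weeks fixes the detection lag `t0`; by default the first
#'   observed event time (log-linear) or profiled (MLE).
#' @param conf_level confidence level for the reported intervals.
#' @return an object of class `single_hit_fit` with fields
#'   `lambda_per_week`, `half_time_weeks`, `lag_weeks`, `n_events`,
#'   `tail_window`, `standard_error_lambda`, `ci_lambda`, `ci_half_time`,
#'   `method`. Always satisfies
#'   `half_time_weeks * lambda_per_week == log(2)`.
#' @examples
#' sim <- simulate_incidence_cohort(
#'   cohort_spec(500, half_time_weeks = 15, lag_weeks = 4,
#'               followup_weeks = 80, seed = 2)
#' )
#' fit_single_hit(sim$table)
#' @export
fit_single_hit <- function(table, group = NULL, tail_window = NULL,
                           method = c("log-linear-tail", "shifted-exp-mle"),
                           lag_weeks = NULL, conf_level = 0.95) {
  method <- match.arg(method)
  if (!is.null(group)) {
    table <- table[table$group == group, , drop = FALSE]
    if (nrow(table) == 0L) {
      stop("no subjects in group '", group, "'", call. = FALSE)
    }
  }
  n_events <- sum(table$event)
  if (n_events == 0L) {
    stop("no events observed; the initiation rate cannot be estimated",
         call. = FALSE)
  }
  first_event <- min(table$time_weeks[table$event == 1])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  if (method == "log-linear-tail") {
    km <- km_estimate(table)
    if (is.null(tail_window)) {
      tail_window <- c(first_event, max(table$time_weeks))
    }
    is_step <- km$n_event > 0 & km$surv > 0 &
      km$time >= tail_window[1] & km$time <= tail_window[2]
    time <- km$time[is_step]
    surv <- km$surv[is_step]
    if (length(unique(time)) < 3L) {
      stop("fewer than 3 distinct event times in the tail window; ",
           "widen the window or use method = \"shifted-exp-mle\"",
           call. = FALSE)
    }
    w <- km$n_risk[is_step]
    ll <- fit_log_survival(time, surv, weights = w)
    lambda <- ll$lambda
    # Greenwood cumulative increments at the retained steps
    g_inc <- ifelse(km$n_event > 0,
                    km$n_event / (km$n_risk * pmax(km$n_risk - km$n_event, 1)),
                    0)
    g_cum <- cumsum(g_inc)[is_step]
    se <- sqrt(greenwood_slope_var(time, w, g_cum))
    lag <- if (is.null(lag_weeks)) first_event else lag_weeks
  } else {
    # shifted-exponential censored MLE
    mle_at <- function(t0) {
      tt <- sum(pmax(table$time_weeks - t0, 0))
      lam <- n_events / tt
      list(lambda = lam, loglik = n_events * log(lam) - lam * tt)
    }
    if (is.null(lag_weeks)) {
      grid <- seq(0, first_event, by = 0.5)
      fits <- lapply(grid, mle_at)
      best <- which.max(vapply(fits, `[[`, numeric(1), "loglik"))
      lag <- grid[best]
      lambda <- fits[[best]]$lambda
    } else {
      if (lag_weeks > first_event) {
        stop("lag_weeks exceeds the first event time; the shifted ",
             "exponential has zero likelihood", call. = FALSE)
      }
      lag <- lag_weeks
      lambda <- mle_at(lag)$lambda
    }
    se <- lambda / sqrt(n_events)
    tail_window <- c(lag, max(table$time_weeks))
  }

  ci_lambda <- c(max(lambda - z * se, .Machine$double.eps),
                 lambda + z * se)
  structure(
    list(lambda_per_week = lambda,
         half_time_weeks = log(2) / lambda,
         lag_weeks = lag,
         n_events = n_events,
         tail_window = tail_window,
         standard_error_lambda = se,
         ci_lambda = ci_lambda,
         ci_half_time = rev(log(2) / ci_lambda),
         conf_level = conf_level,
         method = method,
         group = group),
    class = "single_hit_fit"
  )
}

#' @export
print.single_hit_fit <- function(x, ...) {
  cat("Single-hit initiation kinetics fit (", x$method, ")\n", sep = "")
  cat(sprintf("  rate lambda   : %.5f / week (SE %.5f)\n",
              x$lambda_per_week, x$standard_error_lambda))
  cat(sprintf("  half-time t1/2: %.2f weeks [%.2f, %.2f] (%d%% CI)\n",
              x$half_time_weeks, x$ci_half_time[1], x$ci_half_time[2],
              round(100 * x$conf_level)))
  cat(sprintf("  detection lag : %.2f weeks; events: %d; window: [%g, %g]\n",
              x$lag_weeks, x$n_events, x$tail_window[1], x$tail_window[2]))
  invisible(x)
}

#' Predicted tumor-free survival under a single-hit fit
#'
#' `S(t) = exp(-lambda * max(0, t - t0))`: survival is 1 through the
#' detection lag, then declines exponentially; `S(t0 + t_1/2) = 0.5`.
#'
#' @param fit a [single_hit_fit][fit_single_hit()].
#' @param times times (weeks).
#' @return survival fractions, non-increasing in `times`.
#' @export
predict_survival <- function(fit, times) {
  stopifnot(inherits(fit, "single_hit_fit"))
  exp(-fit$lambda_per_week * pmax(0, times - fit$lag_weeks))
}

#' Write a single-hit fit report as JSON
#'
#' @param fit a [single_hit_fit][fit_single_hit()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "single_hit_fit"))
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
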