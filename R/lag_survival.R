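# Survival analysis of censored single-cell lag times.
#
# A cell's lag is the time from the carbon-source transfer to its first
# budding event; cells that never bud within the microscopy horizon
# (default 20 h) are right-censored at the horizon. Escape curves are
# Kaplan-Meier product-limit estimates, group comparisons use the two-group
# log-rank test, and covariate effects are Cox proportional-hazards fits
# with Breslow tie handling. The standard estimators are delegated to the
# survival package behind this module's interface.

#' Construct a censored single-cell lag table
#'
#' @param data Data frame with columns `cell_id`, `strain`, `lag_h`
#'   (positive; the budding time for events, the observation horizon for
#'   censored cells), `event` (1 = budded, 0 = censored), plus any number of
#'   numeric covariate columns.
#' @return The validated data frame with class `lag_table`.
#' @export
lag_table <- function(data) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  need <- c("cell_id", "strain", "lag_h", "event")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    stop("lag table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(data) == 0) stop("lag table is empty")
  if (anyNA(data$lag_h) || any(data$lag_h <= 0)) {
    stop("`lag_h` must be positive and complete")
  }
  if (!all(data$event %in% c(0, 1))) {
    stop("`event` must be 0 (censored) or 1 (budded)")
  }
  class(data) <- c("lag_table", "data.frame")
  data
}

#' Kaplan-Meier escape curve
#'
#' Product-limit estimate of the probability of still being in the lag phase,
#' honoring censoring. The escape fraction (the cumulative fraction of cells
#' that has escaped the lag phase, as plotted in single-cell lag histograms)
#' is `1 - survival`.
#'
#' @param table A [lag_table()].
#' @return Data frame of class `survival_curve` with columns `time_h`,
#'   `survival`, `at_risk` and `escape`, starting at (0, 1).
#' @export
escape_curve <- function(table) {
  stopifnot(inherits(table, "lag_table"))
  fit <- survival::survfit(survival::Surv(lag_h, event) ~ 1, data = table)
  out <- data.frame(time_h = c(0, fit$time),
                    survival = c(1, fit$surv),
                    at_risk = c(fit$n, fit$n.risk))
  out$escape <- 1 - out$survival
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Summary statistics of single-cell lag times
#'
#' Moments and quartiles are computed over budding events only (censored
#' lags are unknown); the censoring information is carried by
#' `frac_resumed`, the fraction of all cells that resumed growth within the
#' horizon. `noise` is the coefficient of variation of the event lags.
#'
#' @param table A [lag_table()].
#' @param horizon_h Observation horizon in hours (default 20, the usual
#'   microscopy recording window).
#' @return List with `n`, `n_events`, `mean_lag`, `sd_lag`, `min_lag`,
#'   `quartiles` (25/50/75%), `noise` and `frac_resumed`. With zero events
#'   the moments are `NA` and `frac_resumed` is 0.
#' @export
lag_summary <- function(table, horizon_h = 20) {
  stopifnot(inherits(table, "lag_table"))
  ev <- table$lag_h[table$event == 1]
  frac <- mean(table$event == 1 & table$lag_h <= horizon_h)
  if (length(ev) == 0) {
    return(list(n = nrow(table), n_events = 0L, mean_lag = NA_real_,
                sd_lag = NA_real_, min_lag = NA_real_,
                quartiles = stats::setNames(rep(NA_real_, 3),
                                            c("25%", "50%", "75%")),
                noise = NA_real_, frac_resumed = 0))
  }
  m <- mean(ev)
  s <- stats::sd(ev)
  list(n = nrow(table), n_events = length(ev), mean_lag = m, sd_lag = s,
       min_lag = min(ev), quartiles = stats::quantile(ev, c(0.25, 0.5, 0.75)),
       noise = s / m, frac_resumed = frac)
}

#' Two-group log-rank test
#'
#' Compares the lag-time distributions of two tables by the standard
#' log-rank statistic (observed minus expected events under pooled risk
#' sets), 1 degree of freedom.
#'
#' @param a,b [lag_table()] objects for the two groups.
#' @return List of class `logrank_result` with `chi2`, `df` and `p`.
#' @export
logrank_test <- function(a, b) {
  stopifnot(inherits(a, "lag_table"), inherits(b, "lag_table"))
  if (sum(a$event) + sum(b$event) == 0) {
    stop("no events in either group; log-rank test undefined")
  }
  df <- data.frame(lag_h = c(a$lag_h, b$lag_h),
                   event = c(a$event, b$event),
                   group = rep(c("a", "b"), c(nrow(a), nrow(b))))
  sd_ <- survival::survdiff(survival::Surv(lag_h, event) ~ group, data = df)
  structure(list(chi2 = unname(sd_$chisq), df = 1L,
                 p = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank> chi2 = %.4g on %d df, p = %.4g\n", x$chi2, x$df, x$p))
  invisible(x)
}

#' Cox proportional-hazards fit for lag-time covariates
#'
#' Maximizes the Cox partial likelihood (Breslow tie handling by default) for
#' one or two covariates; single-covariate fits carry 1 degree of freedom.
#' A positive coefficient means the covariate accelerates escape from the
#' lag phase (higher hazard of budding).
#'
#' @param table A [lag_table()] containing the covariate column(s).
#' @param covariate Character vector naming one or two covariate columns.
#' @param ties Tie-handling method, `"breslow"` (default) or `"efron"`.
#' @return List of class `cox_result` with `beta`, `se_beta`,
#'   `hazard_ratio` (= exp(beta)), `p` (Wald), `loglik`, `converged` and
#'   `separation` (TRUE when the fit drifted toward an infinite
#'   coefficient, i.e. complete separation).
#' @export
cox_fit <- function(table, covariate, ties = c("breslow", "efron")) {
  stopifnot(inherits(table, "lag_table"))
  ties <- match.arg(ties)
  if (length(covariate) < 1 || length(covariate) > 2) {
    stop("`covariate` must name one or two columns")
  }
  missing <- setdiff(covariate, names(table))
  if (length(missing)) {
    stop("covariate column(s) not found: ", paste(missing, collapse = ", "))
  }
  for (cv in covariate) {
    x <- table[[cv]]
    if (anyNA(x)) stop("covariate `", cv, "` has missing values")
    if (stats::var(as.numeric(x)) == 0) {
      stop("covariate `", cv, "` has no variation")
    }
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(lag_h, event) ~",
    paste(sprintf("`%s`", covariate), collapse = " + ")))
  separation <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = table, ties = ties,
                    control = survival::coxph.control(iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (fit$iter >= 50) {
    grad <- tryCatch(
      sqrt(sum(colSums(as.matrix(stats::residuals(fit, type = "score")))^2)),
      error = function(e) NA_real_)
    stop(sprintf("Cox fit did not converge in 50 iterations (gradient norm %.3g)",
                 grad))
  }
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  names(se) <- names(beta)
  structure(
    list(beta = beta, se_beta = se, hazard_ratio = exp(beta),
         p = 2 * stats::pnorm(-abs(beta / se)),
         loglik = fit$loglik[2], converged = TRUE, separation = separation),
    class = "cox_result"
  )
}

#' @export
print.cox_result <- function(x, ...) {
  cat("<cox_result>\n")
  for (i in seq_along(x$beta)) {
    cat(sprintf("  %s: beta = %.4f (se %.4f), HR = %.3f, p = %.3g\n",
                names(x$beta)[i], x$beta[i], x$se_beta[i],
                x$hazard_ratio[i], x$p[i]))
  }
  if (x$separation) cat("  warning: possible complete separation\n")
  invisible(x)
}
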