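# Malthusian and relative fitness from labeled two-strain competition counts,
# with misclassification correction of the label calls.

#' Construct a competition count table
#'
#' @param data Data frame with columns `time_h`, `count_query`,
#'   `count_reference` (non-negative label counts per time point) and
#'   optionally `total_density` (cells/ml from plating).
#' @return The validated data frame with class `count_table`.
#' @export
count_table <- function(data) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  need <- c("time_h", "count_query", "count_reference")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    stop("count table is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(data) < 1) stop("count table is empty")
  if (any(data$count_query < 0) || any(data$count_reference < 0)) {
    stop("counts must be non-negative")
  }
  class(data) <- c("count_table", "data.frame")
  data
}

#' Label misclassification rates
#'
#' Estimated from control cultures of each competitor growing on its own:
#' the fraction of events called as the other competitor. Typical cytometry
#' gating errors are below 1/5,000 events.
#'
#' @param e_qr Probability that a reference event is called query.
#' @param e_rq Probability that a query event is called reference.
#' @return An object of class `error_rates`. Both rates must lie in
#'   `[0, 0.5)` so the confusion matrix is invertible.
#' @export
error_rates <- function(e_qr = 0, e_rq = 0) {
  if (e_qr < 0 || e_qr >= 0.5 || e_rq < 0 || e_rq >= 0.5) {
    stop("error rates must lie in [0, 0.5)")
  }
  structure(list(e_qr = e_qr, e_rq = e_rq), class = "error_rates")
}

#' Invert label misclassification on observed counts
#'
#' Observed counts arise from true counts through the confusion matrix
#' `[[1 - e_rq, e_qr], [e_rq, 1 - e_qr]]` (columns: true query, true
#' reference). This function solves the linear system for the true counts;
#' negative solutions (possible near zero counts) are clipped to 0 with a
#' warning.
#'
#' @param count_query,count_reference Observed counts (vectors allowed).
#' @param rates An [error_rates()].
#' @return Data frame with corrected `count_query` and `count_reference`.
#' @export
correct_counts <- function(count_query, count_reference, rates = error_rates()) {
  stopifnot(inherits(rates, "error_rates"),
            length(count_query) == length(count_reference))
  det <- 1 - rates$e_qr - rates$e_rq
  if (det <= 0) stop("confusion matrix singular: e_qr + e_rq >= 1")
  # closed-form inverse of the 2x2 confusion matrix
  q <- ((1 - rates$e_qr) * count_query - rates$e_qr * count_reference) / det
  r <- ((1 - rates$e_rq) * count_reference - rates$e_rq * count_query) / det
  if (any(q < 0) || any(r < 0)) {
    warning("corrected counts below zero; clipping to 0")
    q <- pmax(q, 0)
    r <- pmax(r, 0)
  }
  data.frame(count_query = q, count_reference = r)
}

#' Malthusian and relative fitness over one competition episode
#'
#' The Malthusian fitness of each competitor is the natural-log fold change
#' of its subpopulation size between the initial and final time points,
#' where subpopulation size = total density x corrected label fraction.
#' Relative fitness is the query/reference ratio of Malthusian values; the
#' episode duration cancels in the ratio and is therefore not needed.
#'
#' @param initial,final One-row slices of a [count_table()] (or lists with
#'   `count_query`, `count_reference`, `total_density`).
#' @param rates An [error_rates()] applied to both rows.
#' @return Object of class `fitness_result` with `w_query`, `w_reference`
#'   and `rel_fitness`.
#' @export
malthusian_fitness <- function(initial, final, rates = error_rates()) {
  row_sizes <- function(row) {
    if (is.null(row$total_density) || is.na(row$total_density)) {
      stop("both rows need `total_density` from plating")
    }
    cc <- correct_counts(row$count_query, row$count_reference, rates)
    tot <- cc$count_query + cc$count_reference
    if (tot <= 0) stop("row has zero total events")
    c(q = row$total_density * cc$count_query / tot,
      r = row$total_density * cc$count_reference / tot)
  }
  n0 <- row_sizes(initial)
  n1 <- row_sizes(final)
  if (any(c(n0, n1) <= 0)) {
    stop("zero subpopulation size; Malthusian fitness undefined")
  }
  structure(list(w_query = log(n1[["q"]] / n0[["q"]]),
                 w_reference = log(n1[["r"]] / n0[["r"]]),
                 rel_fitness = log(n1[["q"]] / n0[["q"]]) /
                               log(n1[["r"]] / n0[["r"]])),
            class = "fitness_result")
}

#' @export
print.fitness_result <- function(x, ...) {
  cat(sprintf("<fitness_result> w_query = %.4f, w_reference = %.4f, rel = %.4f\n",
              x$w_query, x$w_reference, x$rel_fitness))
  invisible(x)
}

#' Fitness relative to the ancestor
#'
#' Divides a query strain's relative fitness by the ancestral strain's
#' relative fitness measured against the same reference.
#'
#' @param fit,ancestor_fit [malthusian_fitness()] results for the query and
#'   the ancestor run.
#' @return Dimensionless fitness versus the ancestor.
#' @export
fitness_vs_ancestor <- function(fit, ancestor_fit) {
  stopifnot(inherits(fit, "fitness_result"),
            inherits(ancestor_fit, "fitness_result"))
  fit$rel_fitness / ancestor_fit$rel_fitness
}

#' Misclassification-corrected query proportion series
#'
#' Corrected query fraction per time point, for overlay against simulated
#' proportion trajectories. Rows with zero total events are skipped with a
#' warning.
#'
#' @param table A [count_table()].
#' @param rates An [error_rates()].
#' @return Data frame with `time_h` and `p_query`.
#' @export
proportion_series <- function(table, rates = error_rates()) {
  stopifnot(inherits(table, "count_table"))
  tot <- table$count_query + table$count_reference
  keep <- tot > 0
  if (any(!keep)) {
    warning(sum(!keep), " row(s) with zero total events skipped")
  }
  cc <- correct_counts(table$count_query[keep], table$count_reference[keep],
                       rates)
  data.frame(time_h = table$time_h[keep],
             p_query = cc$count_query / (cc$count_query + cc$count_reference))
}

#' Aggregate replicate fitness measurements
#'
#' @param fits List of [malthusian_fitness()] results (biological
#'   replicates).
#' @return List with `mean`, `sd` and `n` of the relative fitness values.
#' @export
aggregate_fitness <- function(fits) {
  vals <- vapply(fits, function(f) f$rel_fitness, numeric(1))
  list(mean = mean(vals), sd = stats::sd(vals), n = length(vals))
}
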