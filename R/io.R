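# Readers and writers for the plain-text formats the pipeline consumes:
# plate-reader CSV (one time column + one column per well), plate-map TSV,
# single-cell lag TSV, competition count TSV, and ON-fraction TSV.

# Convert a time column to decimal hours. Accepts numeric hours or
# "HH:MM:SS" strings (plate-reader export format), auto-detected.
.parse_time_h <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- as.character(x)
  if (all(grepl("^\\s*\\d+:\\d{2}(:\\d{2}(\\.\\d+)?)?\\s*$", x))) {
    parts <- strsplit(trimws(x), ":", fixed = TRUE)
    return(vapply(parts, function(p) {
      p <- as.numeric(p)
      p[1] + p[2] / 60 + (if (length(p) >= 3) p[3] / 3600 else 0)
    }, numeric(1)))
  }
  suppressWarnings(h <- as.numeric(x))
  if (anyNA(h)) stop("cannot parse time column: expected decimal hours or HH:MM:SS")
  h
}

#' Read a plate-reader OD600 CSV
#'
#' Expects a first column named `time_h` (decimal hours) or `time`
#' (HH:MM:SS, auto-detected), and one column of OD600 readings per well.
#' An optional plate map attaches strain/condition labels per well.
#'
#' @param path Path to the CSV file.
#' @param platemap Optional data frame from [read_platemap()] with columns
#'   `well_id`, `strain`, `condition` (and optionally `replicate`).
#' @return Named list of [growth_curve()] objects, one per well column.
#' @export
read_plate_csv <- function(path, platemap = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("plate CSV needs a time column plus at least one well")
  time_h <- .parse_time_h(df[[1]])
  wells <- names(df)[-1]
  curves <- lapply(wells, function(w) {
    strain <- NA_character_; condition <- NA_character_
    if (!is.null(platemap)) {
      row <- platemap[platemap$well_id == w, , drop = FALSE]
      if (nrow(row) == 1) {
        strain <- row$strain
        condition <- row$condition
      }
    }
    growth_curve(time_h, df[[w]], well_id = w, strain = strain,
                 condition = condition)
  })
  names(curves) <- wells
  curves
}

#' Read a plate-map TSV
#'
#' Tab-separated table with columns `well_id`, `strain`, `condition` and
#' optionally `replicate`.
#'
#' @param path Path to the TSV file.
#' @return A data frame.
#' @export
read_platemap <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("well_id", "strain", "condition")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("plate map is missing column(s): ", paste(missing, collapse = ", "))
  }
  df
}

#' Write per-well growth summaries to TSV
#'
#' @param summaries List of [growth_summary()] objects.
#' @param path Output TSV path.
#' @return The combined data frame, invisibly.
#' @export
write_growth_summaries <- function(summaries, path) {
  df <- do.call(rbind, lapply(summaries, as.data.frame))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read a censored single-cell lag table from TSV
#'
#' Tab-separated table with header
#' `cell_id  strain  lag_h  event  <covariate...>`; any extra numeric
#' columns are treated as covariates.
#'
#' @param path Path to the TSV file.
#' @return A [lag_table()].
#' @export
read_lag_tsv <- function(path) {
  lag_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Read a two-strain competition count table from TSV
#'
#' Columns: `time_h`, `count_query`, `count_reference` and optionally
#' `total_density` (cells/ml from plating).
#'
#' @param path Path to the TSV file.
#' @return A data frame of class `count_table`.
#' @export
read_count_tsv <- function(path) {
  count_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Read an ON-fraction series from TSV
#'
#' Columns: `initial_condition`, `generations`, `frac_on`. Rows sharing an
#' `initial_condition` label form one series.
#'
#' @param path Path to the TSV file.
#' @return Named list of [on_fraction_series()] objects, one per initial
#'   condition.
#' @export
read_on_fraction_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("initial_condition", "generations", "frac_on")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("ON-fraction TSV is missing column(s): ", paste(missing, collapse = ", "))
  }
  split_df <- split(df, df$initial_condition)
  lapply(split_df, function(d) {
    d <- d[order(d$generations), ]
    on_fraction_series(d$initial_condition[1], d$generations, d$frac_on)
  })
}
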