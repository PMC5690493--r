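#' Summary statistics of a QA outcome population
#'
#' Mean, sample (n-1) standard deviation, min and max, as used for the
#' per-column summary rows of published QA result tables.  Values are
#' retained at full precision; [round_qa()] applies the one-decimal
#' half-away-from-zero rounding used for table reproduction.
#'
#' @param values numeric vector (n >= 1; sd requires n >= 2).
#' @return an object of class `oof_summary` with `n`, `mean`, `sd`,
#'   `min`, `max` (`sd` is `NA` for n = 1).
#' @export
qa_summary <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("empty list of values")
  if (anyNA(values)) stop("values contain NA")
  structure(list(n = length(values), mean = mean(values),
                 sd = if (length(values) >= 2) stats::sd(values) else NA_real_,
                 min = min(values), max = max(values)),
            class = "oof_summary")
}

#' @export
print.oof_summary <- function(x, ...) {
  cat(sprintf("n = %d  mean = %s  sd = %s  min = %s  max = %s\n",
              x$n, format(round_qa(x$mean)),
              if (is.na(x$sd)) "NA" else format(round_qa(x$sd)),
              format(round_qa(x$min)), format(round_qa(x$max))))
  invisible(x)
}

#' Half-away-from-zero rounding to one decimal
#'
#' The rounding convention used to reproduce printed table values
#' (base R's `round()` rounds half to even).
#'
#' @param x numeric.
#' @param digits decimal places (default 1).
#' @return rounded numeric.
#' @export
round_qa <- function(x, digits = 1) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Two-sided TG-119-style confidence limit
#'
#' `mean +/- 1.96 * SD` of a population of dose differences.  Note this
#' is a population spread statement, wider than the usual confidence
#' interval of the mean.
#'
#' @param stats an `oof_summary` (or numeric vector, summarized first).
#' @return numeric length-2 `c(lower, upper)`.
#' @export
cl_two_sided <- function(stats) {
  s <- if (inherits(stats, "oof_summary")) stats else qa_summary(stats)
  if (is.na(s$sd)) stop("confidence limit requires n >= 2")
  c(lower = s$mean - 1.96 * s$sd, upper = s$mean + 1.96 * s$sd)
}

#' One-sided TG-119-style confidence limit for gamma pass rates
#'
#' Two equivalent forms are exposed: `cl` follows the
#' `100 - mean + 1.96 * SD` convention (the shortfall from 100%), and
#' `lower_bound_pass = mean - 1.96 * SD` is the "at least X% of points
#' pass" form.  They always satisfy `cl = 100 - lower_bound_pass`.
#'
#' @param stats an `oof_summary` of pass rates in percent (or a numeric
#'   vector).
#' @return list with `cl` and `lower_bound_pass`, both percent.
#' @export
cl_pass_rate <- function(stats) {
  s <- if (inherits(stats, "oof_summary")) stats else qa_summary(stats)
  if (is.na(s$sd)) stop("confidence limit requires n >= 2")
  list(cl = 100 - s$mean + 1.96 * s$sd,
       lower_bound_pass = s$mean - 1.96 * s$sd)
}

#' Load a packaged QA results table
#'
#' The package ships per-plan gamma pass rates and median dose
#' differences for three comparison campaigns (reconstruction vs
#' biplanar array; array vs TPS; reconstruction vs TPS) keyed by
#' dataset, energy and technique.
#'
#' @param which `"table1"`, `"table2"` or `"table3"`, or a path to a CSV
#'   with the same columns.
#' @return a data.frame.
#' @export
load_qa_table <- function(which = c("table1", "table2", "table3")) {
  if (file.exists(which[1])) return(utils::read.csv(which[1]))
  which <- match.arg(which)
  fname <- switch(which,
                  table1 = "table1_recon_vs_array.csv",
                  table2 = "table2_array_vs_tps.csv",
                  table3 = "table3_recon_vs_tps.csv")
  path <- system.file("extdata", fname, package = "oofrecon")
  if (path == "") stop("packaged table not found: ", fname)
  utils::read.csv(path)
}

#' Summarize a filtered subset of a QA results table
#'
#' @param table data.frame from [load_qa_table()].
#' @param metric column to summarize (e.g. `"local_2_2"`).
#' @param dataset,energy,technique optional filters; each may be a
#'   vector of accepted values, `NULL` means no filtering.
#' @return an `oof_summary` over the matching rows.
#' @export
subset_summary <- function(table, metric, dataset = NULL, energy = NULL,
                           technique = NULL) {
  if (!metric %in% names(table)) stop("unknown metric column: ", metric)
  keep <- rep(TRUE, nrow(table))
  if (!is.null(dataset)) keep <- keep & table$dataset %in% dataset
  if (!is.null(energy)) keep <- keep & table$energy %in% energy
  if (!is.null(technique)) keep <- keep & table$technique %in% technique
  if (!any(keep)) stop("filter matches no rows")
  qa_summary(table[[metric]][keep])
}
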