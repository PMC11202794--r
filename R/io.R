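#' Read a CSV table against a column schema
#'
#' Reads a headed CSV and validates it: all schema columns must be
#' present and numeric, columns listed in `positive` must be strictly
#' positive, and offending rows/columns are named in the error. Extra
#' columns are dropped with a warning.
#'
#' @param path CSV file path.
#' @param columns required column names.
#' @param positive subset of `columns` that must be strictly positive
#'   (e.g. survival times).
#' @return Data frame with the schema columns, in schema order.
#' @export
read_response_table <- function(path, columns, positive = character()) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  d <- tryCatch(read.csv(path), error = function(e) {
    stop_input("could not parse ", path, ": ", conditionMessage(e))
  })
  if (nrow(d) == 0L) stop_input(path, " contains no data rows")
  missing_cols <- setdiff(columns, names(d))
  if (length(missing_cols)) {
    stop_input("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(d), columns)
  if (length(extra)) {
    warning("ignoring extra column(s): ", paste(extra, collapse = ", "))
  }
  d <- d[columns]
  for (cl in columns) {
    if (!is.numeric(d[[cl]])) {
      stop_input("column '", cl, "' is not numeric")
    }
    if (anyNA(d[[cl]])) {
      stop_input("column '", cl, "' has missing values at row(s) ",
                 paste(which(is.na(d[[cl]])), collapse = ", "))
    }
  }
  for (cl in positive) {
    bad <- which(d[[cl]] <= 0)
    if (length(bad)) {
      stop_input("column '", cl, "' must be positive; offending row(s) ",
                 paste(bad, collapse = ", "))
    }
  }
  message(nrow(d), " rows read from ", basename(path))
  d
}

#' Leukemia survival data
#'
#' The bundled 33-patient leukemia dataset: survival time in weeks
#' (`time`), white blood cell count in units of 10,000 (`wbc`), and an
#' indicator for Auer rods and/or significant granulation of the
#' leukemic cells (`ag`; 1 = present, for 17 patients).
#'
#' @return Data frame with columns `time`, `wbc`, `ag` (33 rows).
#' @examples
#' d <- leukemia_data()
#' table(d$ag)
#' @export
leukemia_data <- function() {
  path <- system.file("extdata", "leukemia.csv", package = "predacc")
  suppressMessages(read_response_table(path, c("time", "wbc", "ag"),
                                       positive = "time"))
}

#' Bundled reference table of critical values
#'
#' The calibrated critical values of Delta for gamma = 0.5 and
#' n = 10..40 at levels 0.01, 0.05, 0.10, 0.20, shipped as a regression
#' fixture for [critical_value_table()].
#'
#' @return Data frame with columns `n`, `alpha_0.01`, `alpha_0.05`,
#'   `alpha_0.1`, `alpha_0.2`.
#' @export
reference_critical_values <- function() {
  path <- system.file("extdata", "critical_values_reference.csv",
                      package = "predacc")
  utils::read.csv(path, check.names = FALSE)
}

#' Write a leave-one-out report or simulation summary to disk
#'
#' `format = "csv"` writes the per-observation table (leave-one-out
#' report) or the long-format cell summary (simulation summary) at full
#' precision. `format = "json"` serialises the whole object, numbers
#' unrounded. Both round-trip through [read_report()].
#'
#' @param report a `loo_report` or `sim_summary`.
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (inherits(report, "loo_report")) {
    payload <- list(
      rows = report$rows,
      summary = list(
        n = report$record$n, gamma = report$gamma, alpha = report$alpha,
        kappa = report$record$kappa, delta = report$record$delta,
        avg_credibility = report$record$avg_credibility,
        e_value = report$e_value$e_value,
        delta_critical = unname(report$delta_critical),
        decision_fbst = report$decisions$fbst,
        decision_delta_rule = report$decisions$delta_rule
      )
    )
    tab <- report$rows
  } else if (inherits(report, "sim_summary")) {
    payload <- list(cells = as.data.frame(report))
    tab <- as.data.frame(report)
  } else {
    stop_input("report must be a loo_report or sim_summary")
  }
  if (format == "csv") {
    write.csv(format(tab, digits = 17, scientific = FALSE, trim = TRUE),
              path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    read.csv(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
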