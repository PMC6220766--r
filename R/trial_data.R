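#' Trial datasets for cost-effectiveness analysis with missing data
#'
#' A `trial_data` object holds patient-level records from a K-arm trial with
#' repeated quality-of-life (QoL) assessments on the health-utility scale
#' (EQ-5D-3L style, negative values permitted), an aggregate cost, baseline
#' covariates (age, sex, and an ordinal 5-level morbidity index that may be
#' incompletely observed), and follow-up durations expressed as fractions of
#' a year.  Missingness indicators are derived from the data, never stored
#' independently: `r_j = 1` exactly when `qol_j` is present and `s = 1`
#' exactly when `cost` is present.
#'
#' @param df data frame with columns `id`, `arm`, the declared covariates,
#'   `qol_1 ... qol_J`, `cost`, and `t_1 ... t_J` (durations).  Missing
#'   values are `NA`.
#' @param J number of follow-up QoL assessments.
#' @param K number of arms; arm 1 is the reference/control arm.
#' @param covariates character vector naming the baseline covariates present
#'   (any of `"age"`, `"sex"`, `"hardman"`).
#' @param qol_range optional interval; when supplied, QoL values outside it
#'   are flagged with a warning at construction (see [validate_dataset()],
#'   which can always be run explicitly).
#' @return An object of class `trial_data`: a list with elements `df`
#'   (records, including derived indicator columns `r_1 ... r_J` and `s`),
#'   `J`, `K` and `covariates`.
#' @examples
#' df <- data.frame(id = c("a", "b"), arm = c(1, 2), age = c(70, 75),
#'                  sex = c(1, 0), hardman = c(2, NA),
#'                  qol_1 = c(0.7, NA), qol_2 = c(0.8, 0.6),
#'                  cost = c(12000, NA), t_1 = 0.5, t_2 = 0.375)
#' td <- as_trial_data(df, J = 2, K = 2,
#'                     covariates = c("age", "sex", "hardman"))
#' td$df$r_1  # 1 0
#' @export
as_trial_data <- function(df, J = 2L, K = 2L,
                          covariates = c("age", "sex", "hardman"),
                          qol_range = NULL) {
  if (!is.data.frame(df) || nrow(df) == 0L) stopf("no records")
  J <- as.integer(J); K <- as.integer(K)
  qol_cols <- paste0("qol_", seq_len(J))
  t_cols <- paste0("t_", seq_len(J))
  needed <- c("id", "arm", covariates, qol_cols, "cost", t_cols)
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stopf("schema error: missing mandatory column(s): %s",
          paste(miss, collapse = ", "))
  df <- df[, needed, drop = FALSE]
  df$id <- as.character(df$id)
  for (col in c("arm", covariates, qol_cols, "cost", t_cols)) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(as.character(v)))
      bad <- which(!is.na(v) & v != "" & is.na(vn))
      if (length(bad))
        stopf("parse error: non-numeric value in column '%s' at row %d",
              col, bad[1])
      v <- vn
    }
    df[[col]] <- v
  }
  if (anyNA(df$arm) || any(df$arm < 1 | df$arm > K | df$arm != round(df$arm)))
    stopf("validation error: arm codes must be integers in 1..%d", K)
  df$arm <- as.integer(df$arm)
  if (any(tabulate(df$arm, K) == 0L))
    stopf("validation error: at least one record required per arm")
  for (j in seq_len(J)) df[[paste0("r_", j)]] <- as.integer(!is.na(df[[qol_cols[j]]]))
  df$s <- as.integer(!is.na(df$cost))
  out <- structure(list(df = df, J = J, K = K, covariates = covariates),
                   class = "trial_data")
  # values outside declared ranges are flagged, never silently dropped
  viol <- validate_dataset(out, qol_range = qol_range %||% c(-Inf, Inf))
  if (nrow(viol)) for (m in unique(viol$message)) warnf("%s", m)
  out
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf("<trial_data> %d patients, %d arms, %d QoL timepoints\n",
              nrow(x$df), x$K, x$J))
  cat("  per-arm n:", paste(tabulate(x$df$arm, x$K), collapse = " / "), "\n")
  cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

default_schema <- function(J = 2L) {
  list(id = "id", arm = "arm", age = "age", sex = "sex", hardman = "hardman",
       qol = paste0("qol_", seq_len(J)), cost = "cost",
       durations = paste0("t_", seq_len(J)))
}

#' Load a trial dataset from CSV
#'
#' Reads a patient-level CSV and maps its columns onto the canonical trial
#' layout via a schema.  Empty cells and the literal string `"NA"` are both
#' read as missing; observation indicators are derived from presence.
#'
#' @param path path to a CSV file with a header row.
#' @param schema column-name mapping: a list with entries `id`, `arm`,
#'   optionally `age`, `sex`, `hardman`, plus `qol` (character vector of the
#'   J QoL columns), `cost`, and `durations` (either column names of length
#'   J or a numeric J-vector of shared durations).  Defaults to the
#'   canonical names used by [write_trial_data()].  The schema may also be a
#'   path to a JSON file with the same structure.
#' @param K number of arms (default 2).
#' @return A [as_trial_data()] object.
#' @export
load_trial_data <- function(path, schema = NULL, K = 2L) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (is.character(schema) && length(schema) == 1L)
    schema <- jsonlite::read_json(path = schema, simplifyVector = TRUE)
  raw <- tryCatch(
    utils::read.csv(path, na.strings = c("", "NA"), stringsAsFactors = FALSE),
    error = function(e) stopf("no records (could not read %s: %s)", path,
                              conditionMessage(e)))
  if (nrow(raw) == 0L) stopf("no records")
  if (is.null(schema)) schema <- default_schema(J = length(grep("^qol_", names(raw))))
  J <- length(schema$qol)
  if (J == 0L) stopf("schema error: no QoL columns declared")
  covs <- intersect(c("age", "sex", "hardman"), names(schema))
  need <- c(schema$id, schema$arm, unlist(schema[covs]), schema$qol, schema$cost)
  dur_cols <- is.character(schema$durations)
  if (dur_cols) need <- c(need, schema$durations)
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stopf("schema error: missing mandatory column(s): %s",
          paste(missing_cols, collapse = ", "))
  df <- data.frame(id = raw[[schema$id]], arm = raw[[schema$arm]],
                   stringsAsFactors = FALSE)
  for (v in covs) df[[v]] <- raw[[schema[[v]]]]
  for (j in seq_len(J)) df[[paste0("qol_", j)]] <- raw[[schema$qol[j]]]
  df$cost <- raw[[schema$cost]]
  for (j in seq_len(J)) {
    df[[paste0("t_", j)]] <- if (dur_cols) raw[[schema$durations[j]]]
                             else schema$durations[j]
  }
  as_trial_data(df, J = J, K = K, covariates = covs,
                qol_range = c(-0.594, 1))
}

#' Write a trial dataset to CSV
#'
#' Missing values are written as empty cells; derived indicator columns are
#' not written (they are re-derived on load).
#'
#' @param data a `trial_data` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trial_data <- function(data, path) {
  stopifnot(inherits(data, "trial_data"))
  drop <- c(paste0("r_", seq_len(data$J)), "s")
  utils::write.csv(data$df[, setdiff(names(data$df), drop), drop = FALSE],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate a trial dataset
#'
#' Checks range, indicator-consistency and duration rules without mutating
#' the data.  QoL values outside the declared utility range are reported as
#' warnings (EQ-5D-3L permits negative utilities and unusual instruments may
#' extend the range); structural inconsistencies are errors.
#'
#' @param data a `trial_data` object.
#' @param qol_range numeric length-2 interval of admissible QoL scores.
#' @return A data frame of violations with columns `row`, `field`, `rule`,
#'   `severity` (`"error"` or `"warning"`) and `message`; zero rows when the
#'   dataset is consistent.
#' @export
validate_dataset <- function(data, qol_range = c(-0.594, 1)) {
  df <- data$df
  v <- list()
  add <- function(rows, field, rule, severity, what) {
    if (!length(rows)) return()
    v[[length(v) + 1L]] <<- data.frame(
      row = rows, field = field, rule = rule, severity = severity,
      message = sprintf("%s (row %s, field %s)", what,
                        paste(rows, collapse = ","), field),
      stringsAsFactors = FALSE)
  }
  for (j in seq_len(data$J)) {
    q <- df[[paste0("qol_", j)]]
    r <- df[[paste0("r_", j)]]
    add(which(!is.na(q) & (q < qol_range[1] | q > qol_range[2])),
        paste0("qol_", j), "range", "warning", "QoL score outside declared range")
    add(which((!is.na(q)) != (r == 1L)), paste0("r_", j),
        "indicator-consistency", "error",
        "observation indicator inconsistent with QoL presence")
    tt <- df[[paste0("t_", j)]]
    add(which(is.na(tt) | tt <= 0), paste0("t_", j), "duration-positive",
        "error", "follow-up duration must be strictly positive")
  }
  add(which((!is.na(df$cost)) != (df$s == 1L)), "s", "indicator-consistency",
      "error", "cost indicator inconsistent with cost presence")
  add(which(!is.na(df$cost) & df$cost < 0), "cost", "range", "warning",
      "negative cost")
  if ("hardman" %in% data$covariates) {
    h <- df$hardman
    add(which(!is.na(h) & !(h %in% 1:5)), "hardman", "range", "error",
        "morbidity index must be an integer category in 1..5")
  }
  if (length(v)) do.call(rbind, v)
  else data.frame(row = integer(), field = character(), rule = character(),
                  severity = character(), message = character(),
                  stringsAsFactors = FALSE)
}

#' Summarise missingness by endpoint and arm
#'
#' Tabulates, for each endpoint (each QoL timepoint, cost, and each
#' incomplete covariate), the number and integer percentage of missing
#' values per arm and overall, together with the full cross-endpoint
#' observed/missing pattern table.  Percentages are rounded half-up, the
#' convention of trial reports.
#'
#' @param data a `trial_data` object.
#' @return An object of class `missingness_summary`: a list with `n_per_arm`,
#'   `n_total`, `endpoints` (data frame with per-arm and total missing counts
#'   and percentages) and `pattern` (data frame of observed(`o`)/missing(`m`)
#'   pattern strings across all endpoints with their counts).
#' @export
summarize_missingness <- function(data) {
  stopifnot(inherits(data, "trial_data"))
  df <- data$df
  K <- data$K
  n_arm <- tabulate(df$arm, K)
  n <- nrow(df)
  ep_cols <- c(paste0("qol_", seq_len(data$J)), "cost")
  ep_names <- c(paste0("QoL at timepoint ", seq_len(data$J)), "Cost")
  if ("hardman" %in% data$covariates && anyNA(df$hardman)) {
    ep_cols <- c(ep_cols, "hardman")
    ep_names <- c(ep_names, "Morbidity index")
  }
  rows <- lapply(seq_along(ep_cols), function(i) {
    m <- is.na(df[[ep_cols[i]]])
    by_arm <- vapply(seq_len(K), function(k) sum(m[df$arm == k]), integer(1))
    out <- data.frame(endpoint = ep_names[i], stringsAsFactors = FALSE)
    for (k in seq_len(K)) {
      out[[paste0("n_missing_arm", k)]] <- by_arm[k]
      out[[paste0("pct_missing_arm", k)]] <-
        as.integer(round_half_up(100 * by_arm[k] / n_arm[k]))
    }
    out$n_missing_total <- sum(by_arm)
    out$pct_missing_total <- as.integer(round_half_up(100 * sum(by_arm) / n))
    out
  })
  endpoints <- do.call(rbind, rows)
  pat <- apply(vapply(ep_cols, function(cn) ifelse(is.na(df[[cn]]), "m", "o"),
                      character(n)), 1L, paste, collapse = "")
  pattern <- as.data.frame(table(pattern = pat), stringsAsFactors = FALSE)
  names(pattern)[2] <- "count"
  pattern <- pattern[order(-pattern$count), , drop = FALSE]
  rownames(pattern) <- NULL
  structure(list(n_per_arm = n_arm, n_total = n, endpoint_columns = ep_cols,
                 endpoints = endpoints, pattern = pattern),
            class = "missingness_summary")
}

#' @export
print.missingness_summary <- function(x, ...) {
  K <- length(x$n_per_arm)
  cat("Level of missing data by treatment arm\n")
  cat(sprintf("%-24s", ""),
      paste(sprintf("arm %d", seq_len(K)), collapse = "      "),
      "     total\n")
  cat(sprintf("%-24s", "Number of patients"),
      paste(sprintf("%5d", x$n_per_arm), collapse = "      "),
      sprintf("     %5d", x$n_total), "\n")
  for (i in seq_len(nrow(x$endpoints))) {
    e <- x$endpoints[i, ]
    cells <- vapply(seq_len(K), function(k)
      sprintf("%3d (%d%%)", e[[paste0("n_missing_arm", k)]],
              e[[paste0("pct_missing_arm", k)]]), character(1))
    cat(sprintf("%-24s", e$endpoint), paste(sprintf("%9s", cells), collapse = " "),
        sprintf(" %4d (%d%%)", e$n_missing_total, e$pct_missing_total), "\n")
  }
  cat(sprintf("%d distinct observed/missing patterns across endpoints (%s)\n",
              nrow(x$pattern), paste(x$endpoint_columns, collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.missingness_summary <- function(x, ...) x$endpoints
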