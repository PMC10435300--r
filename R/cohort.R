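# Cohort plumbing: CSV reading with validation, grouped score-by-outcome
# tables, expansion to patient level, and the bundled reference cohort
# reconstructed from published grouped counts and per-score outcome rates.

cohort_cols <- c("record_id", "age", "heart_rate", "sbp", "gcs", "spo2",
                 "fio2", "resp_rate", "died_7d", "died_30d", "icu_admit")

#' Grouped score-by-outcome table
#'
#' The publishable form of a scored cohort: for each score value, the number
#' of patients and the number of 7-day deaths, 30-day deaths and ICU
#' admissions among them.
#'
#' @param score Integer vector of score values.
#' @param n Patients per score value.
#' @param events_7d,events_30d,events_icu Events per score value; each must
#'   not exceed `n`.
#' @return Data frame of class `grouped_score_table`.
#' @export
grouped_score_table <- function(score, n, events_7d, events_30d, events_icu) {
  tb <- data.frame(score = as.integer(score), n = as.integer(n),
                   events_7d = as.integer(events_7d),
                   events_30d = as.integer(events_30d),
                   events_icu = as.integer(events_icu))
  if (anyNA(tb) || any(tb$n < 0))
    stop("grouped_score_table: counts must be complete and nonnegative",
         call. = FALSE)
  for (col in c("events_7d", "events_30d", "events_icu"))
    if (any(tb[[col]] > tb$n) || any(tb[[col]] < 0))
      stop("grouped_score_table: ", col, " must lie in [0, n] for every score",
           call. = FALSE)
  class(tb) <- c("grouped_score_table", "data.frame")
  tb
}

#' Expand a grouped table to patient-level (score, outcome) pairs
#'
#' Emits, for the chosen outcome, `n_i` copies of score `i` of which
#' `events_i` carry a positive label. Total length equals the table's
#' patient total and the labels sum to the table's event total.
#'
#' @param table A `grouped_score_table`.
#' @param outcome One of `"died_7d"`, `"died_30d"`, `"icu_admit"`.
#' @return Data frame with columns `score` and `label` (1 = event).
#' @export
expand_grouped <- function(table, outcome = c("died_7d", "died_30d", "icu_admit")) {
  stopifnot(inherits(table, "grouped_score_table"))
  outcome <- match.arg(outcome)
  ev_col <- paste0("events_", c(died_7d = "7d", died_30d = "30d",
                                icu_admit = "icu")[outcome])
  ev <- table[[ev_col]]
  if (any(ev > table$n))
    stop("expand_grouped: events exceed n in some cell", call. = FALSE)
  data.frame(
    score = rep(table$score, table$n),
    label = unlist(lapply(seq_len(nrow(table)), function(i)
      rep(c(1L, 0L), c(ev[i], table$n[i] - ev[i]))))
  )
}

# Reconstruct integer event counts from per-score rates (%) and stratum
# sizes: nearest-integer rounding (half up), then largest-remainder repair
# so the column sums to the declared total. Any repair moving a cell by
# more than one count means the rates and total are inconsistent — fail.
allocate_events <- function(n, rates_pct, total) {
  stopifnot(length(n) == length(rates_pct))
  exact <- rates_pct * n / 100
  ev <- floor(exact + 0.5)
  shift <- 0L
  while (sum(ev) != total) {
    resid <- exact - ev
    if (sum(ev) < total) {
      i <- which.max(ifelse(ev < n, resid, -Inf))
      ev[i] <- ev[i] + 1
    } else {
      i <- which.min(ifelse(ev > 0, resid, Inf))
      ev[i] <- ev[i] - 1
    }
    shift <- shift + 1L
    if (shift > length(n))
      stop("allocate_events: cannot reconcile rates with total ", total,
           call. = FALSE)
  }
  if (any(abs(ev - floor(exact + 0.5)) > 1))
    stop("allocate_events: repair moved a cell by more than 1; ",
         "rates are inconsistent with the declared total", call. = FALSE)
  if (any(ev < 0) || any(ev > n))
    stop("allocate_events: reconstructed events outside [0, n]", call. = FALSE)
  as.integer(ev)
}

# Published grouped summaries of the 401-patient ED suspected-sepsis cohort:
# per-score patient counts and per-score outcome rates (%), with the
# printed outcome totals used to pin the reconstruction.
reference_tables <- function() {
  list(
    smart = list(
      score = 0:4,
      n = c(50L, 172L, 102L, 51L, 26L),
      rates_7d = c(0.0, 1.7, 10.8, 19.6, 23.1),
      rates_30d = c(0.0, 4.7, 16.7, 35.3, 38.5),
      rates_icu = c(10.0, 12.2, 43.1, 52.9, 73.1)
    ),
    qsofa = list(
      score = 0:3,
      n = c(168L, 132L, 81L, 20L),
      rates_7d = c(3.0, 6.1, 17.3, 15.0),
      rates_30d = c(5.4, 14.4, 24.7, 25.0),
      rates_icu = c(10.7, 35.6, 49.4, 55.0)
    ),
    totals = c(patients = 401L, events_7d = 30L, events_30d = 53L,
               events_icu = 116L)
  )
}

#' Reference cohort as a grouped score table
#'
#' The bundled 401-patient emergency-department suspected-sepsis cohort in
#' grouped form: per-score patient counts together with 7-day mortality,
#' 30-day mortality and ICU-admission event counts reconstructed from the
#' published per-score rates. Reconstruction rounds rate x n to the nearest
#' integer and repairs against the published outcome totals (30 deaths by
#' day 7, 53 by day 30, 116 ICU admissions); construction fails if any cell
#' would need to move by more than one count. For this cohort all six
#' reconstructions reconcile exactly.
#'
#' @param score Which score's distribution: `"smart"` (values 0-4) or
#'   `"qsofa"` (values 0-3).
#' @return A [grouped_score_table()] whose `n` sums to 401.
#' @examples
#' reference_cohort("smart")
#' @export
reference_cohort <- function(score = c("smart", "qsofa")) {
  score <- match.arg(score)
  ref <- reference_tables()
  tt <- ref$totals
  d <- ref[[score]]
  stopifnot(sum(d$n) == tt[["patients"]])
  tb <- grouped_score_table(
    score = d$score, n = d$n,
    events_7d = allocate_events(d$n, d$rates_7d, tt[["events_7d"]]),
    events_30d = allocate_events(d$n, d$rates_30d, tt[["events_30d"]]),
    events_icu = allocate_events(d$n, d$rates_icu, tt[["events_icu"]])
  )
  stopifnot(sum(tb$events_7d) == tt[["events_7d"]],
            sum(tb$events_30d) == tt[["events_30d"]],
            sum(tb$events_icu) == tt[["events_icu"]])
  tb
}

#' Read or write a grouped score table as CSV
#'
#' Plain CSV with columns `score,n,events_7d,events_30d,events_icu`.
#'
#' @param path File path.
#' @export
read_grouped_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("score", "n", "events_7d", "events_30d", "events_icu")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("read_grouped_csv: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  grouped_score_table(d$score, d$n, d$events_7d, d$events_30d, d$events_icu)
}

#' @rdname read_grouped_csv
#' @param table A `grouped_score_table`.
#' @export
write_grouped_csv <- function(table, path) {
  stopifnot(inherits(table, "grouped_score_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

# ---- patient-level CSV ------------------------------------------------------

# Returns NULL for a valid row, otherwise a reason string.
row_problem <- function(r) {
  reasons <- character()
  num <- c("age", "heart_rate", "sbp", "gcs", "spo2", "fio2", "resp_rate",
           "died_7d", "died_30d", "icu_admit")
  nas <- num[vapply(num, function(f) is.na(r[[f]]), logical(1))]
  nas <- setdiff(nas, "fio2")  # NA FiO2 later defaults to room air
  if (length(nas))
    return(paste("missing or non-numeric:", paste(nas, collapse = ", ")))
  if (r$age < 18) reasons <- c(reasons, "age below 18")
  if (r$heart_rate <= 0) reasons <- c(reasons, "heart_rate not positive")
  if (r$sbp <= 0) reasons <- c(reasons, "sbp not positive")
  if (r$gcs != round(r$gcs) || r$gcs < 3 || r$gcs > 15)
    reasons <- c(reasons, "gcs out of range")
  if (r$spo2 <= 0 || r$spo2 > 100) reasons <- c(reasons, "spo2 out of range")
  if (!is.na(r$fio2) && (r$fio2 < 0.21 || r$fio2 > 1))
    reasons <- c(reasons, "fio2 out of range (must be a fraction in [0.21, 1])")
  if (r$resp_rate <= 0) reasons <- c(reasons, "resp_rate not positive")
  for (oc in c("died_7d", "died_30d", "icu_admit"))
    if (!r[[oc]] %in% c(0, 1))
      reasons <- c(reasons, paste(oc, "not binary 0/1"))
  if (length(reasons) == 0 && r$died_7d == 1 && r$died_30d == 0)
    reasons <- "died_7d = 1 but died_30d = 0"
  if (length(reasons)) paste(reasons, collapse = "; ") else NULL
}

#' Read and validate a patient-level cohort CSV
#'
#' Expects the standard cohort dialect: UTF-8, header row, columns
#' `record_id,age,heart_rate,sbp,gcs,spo2,fio2,resp_rate,died_7d,died_30d,icu_admit`,
#' booleans as 0/1. Malformed rows (out-of-range vitals, non-binary
#' outcomes, a 7-day death not also counted as a 30-day death) are excluded
#' with a per-row reason rather than failing the read. A missing `fio2`
#' value or column defaults to room air (0.21). Non-integer ages are
#' floored to whole years.
#'
#' @param path Path to the CSV file.
#' @return List with `records` (validated data frame) and `exclusions`
#'   (data frame of `row`, `record_id`, `reason`).
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path))
    stop("read_cohort_csv: no such file: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(setdiff(cohort_cols, "fio2"), names(d))
  if (length(miss))
    stop("read_cohort_csv: missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!nrow(d))
    stop("read_cohort_csv: empty cohort (no data rows)", call. = FALSE)
  for (col in setdiff(cohort_cols, "record_id"))
    if (col %in% names(d)) d[[col]] <- suppressWarnings(as.numeric(d[[col]]))
  d <- fill_room_air(d)
  d$age <- floor(d$age)

  problems <- lapply(seq_len(nrow(d)), function(i) row_problem(d[i, ]))
  bad <- !vapply(problems, is.null, logical(1))
  exclusions <- data.frame(
    row = which(bad),
    record_id = d$record_id[bad],
    reason = unlist(problems[bad], use.names = FALSE),
    stringsAsFactors = FALSE
  )
  records <- d[!bad, cohort_cols, drop = FALSE]
  rownames(records) <- NULL
  if (!nrow(records))
    stop("read_cohort_csv: empty cohort (all ", nrow(d),
         " rows failed validation)", call. = FALSE)
  if (nrow(exclusions))
    message("read_cohort_csv: excluded ", nrow(exclusions), " of ", nrow(d),
            " row(s); see the exclusion report")
  list(records = records, exclusions = exclusions)
}

#' Write a patient-level cohort CSV
#'
#' @param cohort Data frame with the standard cohort columns.
#' @param path Destination path.
#' @export
write_cohort_csv <- function(cohort, path) {
  miss <- setdiff(cohort_cols, names(cohort))
  if (length(miss))
    stop("write_cohort_csv: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  utils::write.csv(cohort[, cohort_cols], path, row.names = FALSE)
  invisible(path)
}
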