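#' Shock index
#'
#' Ratio of heart rate to systolic blood pressure. Values of 1.0 or more
#' indicate circulatory compromise and score one S-S.M.A.R.T point.
#'
#' @param heart_rate Heart rate in beats/min (> 0). Vectorised.
#' @param sbp Systolic blood pressure in mmHg (> 0). Vectorised.
#' @return Numeric vector `heart_rate / sbp`, unrounded. `NA` inputs
#'   propagate to `NA` outputs.
#' @examples
#' shock_index(110, 100)  # 1.1
#' shock_index(60, 120)   # 0.5
#' @export
shock_index <- function(heart_rate, sbp) {
  if (any(heart_rate <= 0, na.rm = TRUE))
    stop("shock_index: 'heart_rate' must be strictly positive", call. = FALSE)
  if (any(sbp <= 0, na.rm = TRUE))
    stop("shock_index: 'sbp' must be strictly positive", call. = FALSE)
  heart_rate / sbp
}

#' ROX index
#'
#' (SpO2 / FiO2) / respiratory rate, with SpO2 as a percentage and FiO2 as a
#' fraction of inspired oxygen. Low values reflect hypoxaemia, high oxygen
#' requirement or tachypnoea; 10 or below scores one S-S.M.A.R.T point.
#'
#' @param spo2 Oxygen saturation in percent, in (0, 100]. Vectorised.
#' @param fio2 Fraction of inspired oxygen, in [0.21, 1.0] (0.21 = room air).
#'   Values above 1 are rejected rather than rescaled, since an FiO2 given as
#'   a percentage (e.g. 21) would silently shift the index by two orders of
#'   magnitude.
#' @param resp_rate Respiratory rate in breaths/min (> 0). Vectorised.
#' @return Numeric vector `(spo2 / fio2) / resp_rate`, unrounded.
#' @examples
#' rox_index(98, 0.21, 14)  # about 33.3, healthy room-air breathing
#' rox_index(90, 0.40, 30)  # 7.5, below the <=10 cutoff
#' @export
rox_index <- function(spo2, fio2, resp_rate) {
  if (any(spo2 <= 0 | spo2 > 100, na.rm = TRUE))
    stop("rox_index: 'spo2' must be in (0, 100] percent", call. = FALSE)
  if (any(fio2 > 1, na.rm = TRUE))
    stop("rox_index: 'fio2' must be a fraction in [0.21, 1.0]; ",
         "values > 1 look like percentages (e.g. 21 instead of 0.21)",
         call. = FALSE)
  if (any(fio2 < 0.21, na.rm = TRUE))
    stop("rox_index: 'fio2' below 0.21 (room air) is not physical",
         call. = FALSE)
  if (any(resp_rate <= 0, na.rm = TRUE))
    stop("rox_index: 'resp_rate' must be strictly positive", call. = FALSE)
  (spo2 / fio2) / resp_rate
}

# ---- score configurations ---------------------------------------------------

#' Build a score configuration
#'
#' A score configuration is an ordered set of components, each awarding a
#' fixed number of points when a derived quantity satisfies an inclusive
#' threshold comparison.
#'
#' @param name Label for the score (e.g. `"smart"`).
#' @param components A data frame with columns `name` (component label),
#'   `input` (one of `"shock_index"`, `"rox_index"`, `"age"`, `"gcs"`,
#'   `"heart_rate"`, `"sbp"`, `"spo2"`, `"fio2"`, `"resp_rate"`), `op`
#'   (`"ge"` or `"le"`, both inclusive), `threshold` (numeric) and `points`
#'   (nonnegative integer).
#' @return An object of class `score_config`.
#' @seealso [config_smart()], [config_qsofa()], [read_score_config()]
#' @export
score_config <- function(name, components) {
  components <- as.data.frame(components, stringsAsFactors = FALSE)
  needed <- c("name", "input", "op", "threshold", "points")
  missing_cols <- setdiff(needed, names(components))
  if (length(missing_cols))
    stop("score_config: components missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  valid_inputs <- c("shock_index", "rox_index", "age", "gcs", "heart_rate",
                    "sbp", "spo2", "fio2", "resp_rate")
  bad <- setdiff(components$input, valid_inputs)
  if (length(bad))
    stop("score_config: unknown input(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!all(components$op %in% c("ge", "le")))
    stop("score_config: 'op' must be \"ge\" or \"le\"", call. = FALSE)
  if (any(components$points < 0) || any(components$points != round(components$points)))
    stop("score_config: 'points' must be nonnegative integers", call. = FALSE)
  components$points <- as.integer(components$points)
  structure(list(name = name, components = components), class = "score_config")
}

#' @export
print.score_config <- function(x, ...) {
  cat("Score configuration:", x$name, "\n")
  comp <- x$components
  op_sym <- ifelse(comp$op == "ge", ">=", "<=")
  for (i in seq_len(nrow(comp)))
    cat(sprintf("  %-14s %s %s %g -> %d point(s)\n", comp$name[i],
                comp$input[i], op_sym[i], comp$threshold[i], comp$points[i]))
  invisible(x)
}

#' Default S-S.M.A.R.T configuration
#'
#' Four one-point criteria assessed at triage: shock index >= 1.0,
#' GCS <= 14 (altered mental status), age >= 65 years, ROX index <= 10.
#' All comparisons are inclusive, so a value exactly at threshold scores.
#'
#' @return A `score_config` named `"smart"` with maximum score 4.
#' @export
config_smart <- function() {
  score_config("smart", data.frame(
    name      = c("shock", "mental_status", "age", "rox"),
    input     = c("shock_index", "gcs", "age", "rox_index"),
    op        = c("ge", "le", "ge", "le"),
    threshold = c(1.0, 14, 65, 10),
    points    = c(1L, 1L, 1L, 1L),
    stringsAsFactors = FALSE
  ))
}

#' Default qSOFA configuration
#'
#' The Sepsis-3 bedside operationalisation: respiratory rate >= 22/min,
#' systolic blood pressure <= 100 mmHg, GCS <= 14 (altered mentation), one
#' point each.
#'
#' @return A `score_config` named `"qsofa"` with maximum score 3.
#' @export
config_qsofa <- function() {
  score_config("qsofa", data.frame(
    name      = c("resp_rate", "hypotension", "mental_status"),
    input     = c("resp_rate", "sbp", "gcs"),
    op        = c("ge", "le", "le"),
    threshold = c(22, 100, 14),
    points    = c(1L, 1L, 1L),
    stringsAsFactors = FALSE
  ))
}

# base vitals fields each derived input requires
input_fields <- function(input) {
  switch(input,
    shock_index = c("heart_rate", "sbp"),
    rox_index   = c("spo2", "fio2", "resp_rate"),
    input)
}

#' Fields a configuration needs
#' @param config A `score_config`.
#' @return Character vector of raw vitals column names.
#' @export
required_fields <- function(config) {
  stopifnot(inherits(config, "score_config"))
  unique(unlist(lapply(config$components$input, input_fields)))
}

# compute the derived quantity for one component over a vitals data frame
component_value <- function(input, data) {
  switch(input,
    shock_index = shock_index(data$heart_rate, data$sbp),
    rox_index   = rox_index(data$spo2, data$fio2, data$resp_rate),
    data[[input]])
}

#' Apply a score configuration to triage vitals
#'
#' Core scorer: evaluates every component of `config` against the rows of
#' `data` and sums the points of satisfied criteria. Comparisons are inclusive
#' and performed at full floating precision (no intermediate rounding of
#' shock or ROX index).
#'
#' @param data A data frame (or coercible named list) holding the raw vitals
#'   columns named by [required_fields()]. Non-integer ages are floored to
#'   whole years.
#' @param config A `score_config`.
#' @return Integer vector of scores, one per row. Rows with a missing
#'   required field raise an error naming the fields; use [score_cohort()]
#'   for complete-case handling across a cohort.
#' @examples
#' apply_score(data.frame(age = 70, heart_rate = 120, sbp = 90, gcs = 13,
#'                        spo2 = 90, fio2 = 0.40, resp_rate = 30),
#'             config_smart())  # 4
#' @export
apply_score <- function(data, config) {
  stopifnot(inherits(config, "score_config"))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  req <- required_fields(config)
  absent <- setdiff(req, names(data))
  if (length(absent))
    stop("apply_score (", config$name, "): missing required field(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  na_fields <- req[vapply(req, function(f) anyNA(data[[f]]), logical(1))]
  if (length(na_fields))
    stop("apply_score (", config$name, "): missing value(s) in field(s): ",
         paste(na_fields, collapse = ", "), call. = FALSE)
  if ("age" %in% names(data)) data$age <- floor(data$age)
  comp <- config$components
  total <- integer(nrow(data))
  for (i in seq_len(nrow(comp))) {
    v <- component_value(comp$input[i], data)
    hit <- if (comp$op[i] == "ge") v >= comp$threshold[i] else v <= comp$threshold[i]
    total <- total + as.integer(hit) * comp$points[i]
  }
  as.integer(total)
}

#' S-S.M.A.R.T score of one or more triage records
#'
#' @param record A named list or data frame of triage vitals (`age`,
#'   `heart_rate`, `sbp`, `gcs`, `spo2`, `fio2`, `resp_rate`).
#' @param config Score configuration; defaults to [config_smart()].
#' @return Integer score(s) in 0..4 under the default configuration.
#' @examples
#' smart_score(list(age = 70, heart_rate = 120, sbp = 90, gcs = 13,
#'                  spo2 = 90, fio2 = 0.40, resp_rate = 30))  # 4
#' @export
smart_score <- function(record, config = config_smart()) {
  apply_score(record, config)
}

#' qSOFA score of one or more triage records
#'
#' @param record A named list or data frame with at least `resp_rate`, `sbp`
#'   and `gcs`.
#' @param config Score configuration; defaults to [config_qsofa()].
#' @return Integer score(s) in 0..3 under the default configuration.
#' @export
qsofa_score <- function(record, config = config_qsofa()) {
  apply_score(record, config)
}

#' Score a cohort under one or more configurations
#'
#' Complete-case scoring: records missing any field required by any
#' configuration are excluded and reported, not imputed. Missing FiO2 is the
#' one exception — it is taken as room air (0.21) with a note, since charts
#' routinely omit FiO2 for patients not on oxygen.
#'
#' @param records Data frame of triage records; must carry a `record_id`
#'   column, the vitals needed by `configs`, and optionally the outcome
#'   columns `died_7d`, `died_30d`, `icu_admit` (copied through).
#' @param configs List of `score_config` objects; defaults to the
#'   S-S.M.A.R.T and qSOFA pair. List names default to each config's name.
#' @return Data frame with `record_id`, one integer column per score, and
#'   any outcome columns, one row per complete-case record. The exclusion
#'   report (a data frame of `record_id`, `reason`) is attached as
#'   attribute `"exclusions"`.
#' @export
score_cohort <- function(records, configs = list(config_smart(), config_qsofa())) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!nrow(records))
    stop("score_cohort: empty cohort", call. = FALSE)
  if (inherits(configs, "score_config")) configs <- list(configs)
  if (is.null(names(configs)) || any(!nzchar(names(configs))))
    names(configs) <- vapply(configs, `[[`, character(1), "name")
  if (!"record_id" %in% names(records))
    records$record_id <- sprintf("R%04d", seq_len(nrow(records)))

  records <- fill_room_air(records)
  req <- unique(unlist(lapply(configs, required_fields)))
  absent <- setdiff(req, names(records))
  if (length(absent))
    stop("score_cohort: missing required column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)

  incomplete <- lapply(seq_len(nrow(records)), function(i) {
    miss <- req[vapply(req, function(f) is.na(records[[f]][i]), logical(1))]
    if (length(miss))
      data.frame(record_id = records$record_id[i],
                 reason = paste("missing", paste(miss, collapse = ", ")),
                 stringsAsFactors = FALSE)
  })
  exclusions <- do.call(rbind, incomplete)
  if (is.null(exclusions))
    exclusions <- data.frame(record_id = character(), reason = character(),
                             stringsAsFactors = FALSE)
  keep <- !records$record_id %in% exclusions$record_id
  if (!any(keep))
    stop("score_cohort: no complete-case records left after exclusions",
         call. = FALSE)
  complete <- records[keep, , drop = FALSE]

  out <- data.frame(record_id = complete$record_id, stringsAsFactors = FALSE)
  for (nm in names(configs))
    out[[nm]] <- apply_score(complete, configs[[nm]])
  for (oc in intersect(c("died_7d", "died_30d", "icu_admit"), names(complete)))
    out[[oc]] <- complete[[oc]]
  rownames(out) <- NULL
  attr(out, "exclusions") <- exclusions
  out
}

# room-air default: absent or NA FiO2 becomes 0.21, with a logged note
fill_room_air <- function(records) {
  if (!"fio2" %in% names(records)) {
    message("fio2 column absent; assuming room air (FiO2 = 0.21) for all records")
    records$fio2 <- 0.21
  } else if (anyNA(records$fio2)) {
    n <- sum(is.na(records$fio2))
    message(n, " record(s) without FiO2; assuming room air (FiO2 = 0.21)")
    records$fio2[is.na(records$fio2)] <- 0.21
  }
  records
}

# ---- configuration serialisation --------------------------------------------

#' Read or write a score configuration file
#'
#' Configurations round-trip through YAML or JSON (chosen by file
#' extension) as `name` plus a `components` list of
#' `{name, input, op, threshold, points}` entries.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_score_config()` returns a `score_config`;
#'   `write_score_config()` returns `path` invisibly.
#' @export
read_score_config <- function(path) {
  if (!file.exists(path))
    stop("read_score_config: no such file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  comp <- raw$components
  if (is.list(comp) && !is.data.frame(comp))
    comp <- do.call(rbind, lapply(comp, as.data.frame, stringsAsFactors = FALSE))
  score_config(raw$name, comp)
}

#' @rdname read_score_config
#' @param config A `score_config` to serialise.
#' @export
write_score_config <- function(config, path) {
  stopifnot(inherits(config, "score_config"))
  comp <- config$components
  payload <- list(
    name = config$name,
    components = lapply(seq_len(nrow(comp)), function(i) list(
      name = comp$name[i], input = comp$input[i], op = comp$op[i],
      threshold = comp$threshold[i], points = comp$points[i]))
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(payload, path)
  }
  invisible(path)
}
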