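# Deterministic synthetic triage-vitals simulator. Each stratum targets an
# exact S-S.M.A.R.T score: a random subset of criteria of the right size is
# chosen per patient and each vital is drawn uniformly from a range that
# satisfies (or fails) its criterion, so re-scoring reproduces the target
# histogram exactly. Simplicity over physiological realism: vitals are
# independent across criteria and uniform within range.

#' Simulation specification
#'
#' Targets for [simulate_cohort()]: how many patients per S-S.M.A.R.T score
#' value (0-4) and how many 7-day deaths, 30-day deaths and ICU admissions
#' within each stratum. Defaults reproduce the bundled reference cohort
#' ([reference_cohort()]): 401 patients distributed 50/172/102/51/26 over
#' scores 0-4 with the reconstructed per-stratum event counts.
#'
#' @param n_per_score Integer vector of patients per score 0, 1, ..., up to
#'   the score maximum (4 criteria, so at most 5 strata).
#' @param events_7d,events_30d,events_icu Events per stratum; each at most
#'   `n_per_score`, and 7-day deaths at most 30-day deaths (a death within 7
#'   days is also a death within 30).
#' @param seed Integer seed driving all sampling; default 20230810.
#' @return Object of class `sim_spec`.
#' @export
sim_spec <- function(n_per_score,
                     events_7d = integer(length(n_per_score)),
                     events_30d = integer(length(n_per_score)),
                     events_icu = integer(length(n_per_score)),
                     seed = 20230810) {
  n_per_score <- as.integer(n_per_score)
  if (length(n_per_score) > 5L)
    stop("sim_spec: at most 5 strata (scores 0-4); a target score above 4 ",
         "is infeasible with four one-point criteria", call. = FALSE)
  lens <- lengths(list(events_7d, events_30d, events_icu))
  if (any(lens != length(n_per_score)))
    stop("sim_spec: event vectors must match n_per_score in length",
         call. = FALSE)
  if (any(n_per_score < 0))
    stop("sim_spec: negative stratum size", call. = FALSE)
  for (ev in list(events_7d, events_30d, events_icu))
    if (any(ev < 0) || any(ev > n_per_score))
      stop("sim_spec: stratum events must lie in [0, n]", call. = FALSE)
  if (any(events_7d > events_30d))
    stop("sim_spec: events_7d cannot exceed events_30d in any stratum",
         call. = FALSE)
  structure(list(n_per_score = n_per_score,
                 events_7d = as.integer(events_7d),
                 events_30d = as.integer(events_30d),
                 events_icu = as.integer(events_icu),
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Specification reproducing the reference cohort
#'
#' @param seed Seed forwarded to [sim_spec()].
#' @return A `sim_spec` whose targets are the reference cohort's
#'   S-S.M.A.R.T strata and per-stratum event counts.
#' @export
sim_spec_reference <- function(seed = 20230810) {
  tb <- reference_cohort("smart")
  sim_spec(tb$n, tb$events_7d, tb$events_30d, tb$events_icu, seed = seed)
}

# Sampling ranges per criterion. Ranges are chosen so that a draw can never
# accidentally flip the criterion: satisfied and unsatisfied ranges are
# disjoint in the derived quantity.
sample_criterion <- function(criterion, satisfied, k) {
  switch(criterion,
    shock = if (satisfied) {
      sbp <- sample(70:100, k, replace = TRUE)           # hypotensive-ish
      list(sbp = sbp,
           heart_rate = sbp + sample(0:70, k, replace = TRUE))  # HR >= SBP
    } else {
      sbp <- sample(101:140, k, replace = TRUE)
      list(sbp = sbp,
           heart_rate = sbp - sample(1:45, k, replace = TRUE))  # HR < SBP
    },
    mental = list(gcs = if (satisfied) sample(3:14, k, replace = TRUE)
                  else rep(15L, k)),
    age = list(age = if (satisfied) sample(65:95, k, replace = TRUE)
               else sample(18:64, k, replace = TRUE)),
    rox = if (satisfied) {
      # high oxygen need, low saturation, tachypnoea: ROX <= 95/0.5/24 < 8
      list(spo2 = sample(80:95, k, replace = TRUE),
           fio2 = round(stats::runif(k, 0.5, 1.0), 2),
           resp_rate = sample(24:40, k, replace = TRUE))
    } else {
      # room air, good saturation, normal rate: ROX >= 94/0.21/20 > 22
      list(spo2 = sample(94:100, k, replace = TRUE),
           fio2 = rep(0.21, k),
           resp_rate = sample(10:20, k, replace = TRUE))
    })
}

#' Simulate a triage cohort hitting exact score strata
#'
#' Generates patient-level triage records whose default S-S.M.A.R.T scores
#' reproduce the specification's per-score counts exactly. For each patient
#' a subset of the four criteria of the target size is drawn uniformly,
#' then each vital is sampled from a range that cleanly satisfies or fails
#' its criterion (the function asserts the re-scored stratum). Outcomes are
#' assigned to random patients within each stratum, with 7-day deaths
#' nested inside 30-day deaths; ICU admission is drawn independently of
#' death (no joint distribution is targeted). The caller's RNG state is
#' left untouched.
#'
#' @param spec A [sim_spec()].
#' @return Data frame in the standard cohort layout with `record_id`s
#'   `SIM-0001`, `SIM-0002`, ... Running it twice with the same spec gives
#'   identical output.
#' @examples
#' cohort <- simulate_cohort(sim_spec(c(2, 2, 1), seed = 1))
#' table(smart_score(cohort))
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  criteria <- c("shock", "mental", "age", "rox")
  strata <- list()
  for (s in seq_along(spec$n_per_score)) {
    target <- s - 1L
    k <- spec$n_per_score[s]
    if (k == 0L) next
    # which criteria each patient satisfies: a uniform size-`target` subset
    hit <- matrix(FALSE, k, 4, dimnames = list(NULL, criteria))
    for (i in seq_len(k))
      if (target > 0) hit[i, sample.int(4, target)] <- TRUE
    block <- data.frame(row.names = seq_len(k))
    for (cr in criteria) {
      for (sat in c(TRUE, FALSE)) {
        idx <- which(hit[, cr] == sat)
        if (!length(idx)) next
        draw <- sample_criterion(cr, sat, length(idx))
        for (fld in names(draw)) {
          if (is.null(block[[fld]])) block[[fld]] <- NA_real_
          block[[fld]][idx] <- draw[[fld]]
        }
      }
    }
    # outcome assignment: 30-day deaths drawn first, 7-day deaths nested
    block$died_30d <- 0L; block$died_7d <- 0L; block$icu_admit <- 0L
    d30 <- sample.int(k, spec$events_30d[s])
    block$died_30d[d30] <- 1L
    block$died_7d[d30[seq_len(spec$events_7d[s])]] <- 1L
    block$icu_admit[sample.int(k, spec$events_icu[s])] <- 1L
    block$.target <- target
    strata[[length(strata) + 1L]] <- block
  }
  if (!length(strata)) {
    empty <- data.frame(matrix(nrow = 0, ncol = length(cohort_cols)))
    names(empty) <- cohort_cols
    return(empty)
  }
  cohort <- do.call(rbind, strata)
  cohort$record_id <- sprintf("SIM-%04d", seq_len(nrow(cohort)))
  rescored <- apply_score(cohort, config_smart())
  if (!all(rescored == cohort$.target))
    stop("simulate_cohort: internal error - re-scored stratum mismatch",
         call. = FALSE)
  cohort$.target <- NULL
  rownames(cohort) <- NULL
  cohort[, cohort_cols]
}
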