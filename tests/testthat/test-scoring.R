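test_that("shock and ROX indices compute unrounded ratios and reject bad inputs", {
  expect_equal(shock_index(100, 100), 1.0)
  expect_equal(shock_index(110, 100), 1.1)
  expect_equal(shock_index(60, 120), 0.5)
  expect_error(shock_index(-5, 100), "heart_rate")
  expect_error(shock_index(100, 0), "sbp")

  expect_equal(rox_index(98, 0.21, 14), 98 / 0.21 / 14)
  expect_equal(rox_index(90, 0.40, 30), 7.5)
  expect_equal(rox_index(100, 1.0, 10), 10.0)
  expect_error(rox_index(98, 21, 14), "percentage")  # FiO2 given in percent
  expect_error(rox_index(98, 0.10, 14), "room air")
  expect_error(rox_index(0, 0.21, 14), "spo2")
  expect_error(rox_index(98, 0.21, 0), "resp_rate")
})

test_that("S-S.M.A.R.T score counts satisfied criteria with inclusive boundaries", {
  all_four <- make_record(age = 70, heart_rate = 120, sbp = 90, gcs = 13,
                          spo2 = 90, fio2 = 0.40, resp_rate = 30)
  expect_identical(smart_score(all_four), 4L)
  expect_identical(smart_score(make_record()), 0L)
  # every component exactly at threshold scores (>= / <= are inclusive)
  boundary <- make_record(age = 65, heart_rate = 100, sbp = 100, gcs = 14,
                          spo2 = 100, fio2 = 1.0, resp_rate = 10)
  expect_identical(smart_score(boundary), 4L)
  # non-integer age floors to whole years: 64.9 -> 64, below the cutoff
  expect_identical(smart_score(make_record(age = 64.9)), 0L)
  expect_identical(smart_score(make_record(age = 65.0)), 1L)
})

test_that("qSOFA score applies Sepsis-3 thresholds inclusively", {
  expect_identical(qsofa_score(make_record(resp_rate = 22, sbp = 100, gcs = 14)), 3L)
  expect_identical(qsofa_score(make_record(resp_rate = 16, sbp = 130, gcs = 15)), 0L)
  expect_identical(qsofa_score(make_record(resp_rate = 24, sbp = 120, gcs = 15)), 1L)
})

test_that("missing required fields raise an error naming them", {
  rec <- make_record()
  rec$gcs <- NA
  expect_error(smart_score(rec), "gcs")
  rec2 <- make_record()
  rec2$sbp <- NULL
  expect_error(qsofa_score(rec2), "sbp")
})

test_that("worsening any single vital never decreases either score", {
  set.seed(11)
  worse <- list(
    age = function(r) { r$age <- r$age + sample(1:20, 1); r },
    heart_rate = function(r) { r$heart_rate <- r$heart_rate + sample(5:40, 1); r },
    sbp = function(r) { r$sbp <- max(40, r$sbp - sample(5:40, 1)); r },
    gcs = function(r) { r$gcs <- max(3, r$gcs - sample(1:5, 1)); r },
    spo2 = function(r) { r$spo2 <- max(50, r$spo2 - sample(1:20, 1)); r },
    fio2 = function(r) { r$fio2 <- min(1, r$fio2 + runif(1, 0.1, 0.5)); r },
    resp_rate = function(r) { r$resp_rate <- r$resp_rate + sample(2:15, 1); r }
  )
  for (i in 1:60) {
    rec <- make_record(age = sample(18:90, 1), heart_rate = sample(50:150, 1),
                       sbp = sample(70:160, 1), gcs = sample(3:15, 1),
                       spo2 = sample(70:100, 1),
                       fio2 = round(runif(1, 0.21, 0.9), 2),
                       resp_rate = sample(8:35, 1))
    perturb <- worse[[sample(names(worse), 1)]]
    rec2 <- perturb(rec)
    expect_gte(smart_score(rec2), smart_score(rec))
    expect_gte(qsofa_score(rec2), qsofa_score(rec))
    expect_true(smart_score(rec) %in% 0:4)
    expect_true(qsofa_score(rec) %in% 0:3)
  }
})

test_that("score configurations round-trip through YAML and JSON unchanged", {
  set.seed(3)
  cohort <- simulate_cohort(sim_spec(c(8, 8, 8, 8, 8), seed = 3))
  for (ext in c("yaml", "json")) {
    for (cfg in list(config_smart(), config_qsofa())) {
      path <- file.path(tempdir(), paste0(cfg$name, ".", ext))
      write_score_config(cfg, path)
      reloaded <- read_score_config(path)
      expect_identical(apply_score(cohort, reloaded), apply_score(cohort, cfg))
    }
  }
})

test_that("score_cohort is complete-case with a reasoned exclusion report", {
  cohort <- make_cohort(3)
  scored <- score_cohort(cohort)
  expect_identical(dim(scored), c(3L, 6L))  # id + 2 scores + 3 outcomes
  expect_named(scored, c("record_id", "smart", "qsofa",
                         "died_7d", "died_30d", "icu_admit"))

  cohort$gcs[2] <- NA
  scored <- score_cohort(cohort)
  expect_identical(nrow(scored), 2L)
  excl <- attr(scored, "exclusions")
  expect_identical(excl$record_id, "R02")
  expect_match(excl$reason, "gcs")

  cohort$gcs <- NA
  expect_error(score_cohort(cohort), "no complete-case")
})

test_that("absent FiO2 defaults to room air with a note", {
  cohort <- make_cohort(2)
  cohort$fio2 <- NULL
  expect_message(scored <- score_cohort(cohort), "room air")
  expect_identical(nrow(scored), 2L)
  cohort2 <- make_cohort(2)
  cohort2$fio2[1] <- NA
  expect_message(score_cohort(cohort2), "room air")
})
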