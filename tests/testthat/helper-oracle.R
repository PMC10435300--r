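# Independent brute-force AUC oracle: average over all event/non-event
# pairs with half credit for ties. Deliberately O(mn) and unrelated to the
# midrank implementation it checks.
auc_pair_oracle <- function(scores, labels) {
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Random tied-integer scored instance with both classes present.
random_scored <- function(n, max_score = 5) {
  scores <- sample(0:max_score, n, replace = TRUE)
  labels <- sample(c(0, 1), n, replace = TRUE)
  labels[sample.int(n, 1)] <- 1
  labels[sample(setdiff(seq_len(n), which(labels == 1)[1]), 1)] <- 0
  list(scores = scores, labels = labels)
}

# A complete, valid triage record; override fields as needed.
make_record <- function(...) {
  rec <- list(record_id = "R1", age = 40, heart_rate = 80, sbp = 120,
              gcs = 15, spo2 = 98, fio2 = 0.21, resp_rate = 16,
              died_7d = 0, died_30d = 0, icu_admit = 0)
  utils::modifyList(rec, list(...))
}

make_cohort <- function(n = 5, ...) {
  rows <- lapply(seq_len(n), function(i) {
    r <- make_record(record_id = sprintf("R%02d", i))
    as.data.frame(r, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
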