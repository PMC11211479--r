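# Shared fixtures built in code: tiny hand-enumerable timelines and a
# cached small synthetic population for property tests.

DAY <- 1440

# minutes-from-epoch for "day d at hour h"
dh <- function(d, h = 0, m = 0) d * DAY + h * 60 + m

# one-patient timeline with configurable admission and events
tiny_timelines <- function() {
  persons <- data.frame(
    patient_id = c("p1", "p2"),
    birth_date = c(dh(-8000), dh(-12000)),
    sex = c("F", "M"), site = "A")
  events <- data.frame(
    patient_id = c("p1", "p1", "p1", "p2", "p2"),
    time = c(dh(1, 9), dh(2, 9), dh(3, 9), dh(1, 12), dh(2, 18)),
    code = c("DX/001", "LAB/GLU", "DX/002", "DX/001", "DX/003"),
    value = c(NA, 4.5, NA, NA, NA))
  admissions <- data.frame(
    patient_id = c("p1", "p2"),
    admit_time = c(dh(1, 8), dh(1, 10)),
    discharge_time = c(dh(4, 11), dh(3, 9)),
    death_time = c(NA_real_, NA_real_))
  timelineSet(persons, events, admissions)
}

# the 6-admission cohort fixture exercising every eligibility rule:
#   a1 under-age (site floor 28 days)
#   a2 under-age
#   a3 discharged before admission-day midnight
#   a4 eligible, LOS exactly 7 days, glucose 2.9 on day 2
#   a5 eligible, LOS 6 days, glucose 3.0 on day 2
#   a6 eligible, glucose 2.9 before admission-day midnight (task exclusion),
#      readmitted exactly 30 days post discharge
cohort_fixture <- function() {
  persons <- data.frame(
    patient_id = sprintf("q%d", 1:6),
    birth_date = c(dh(90), dh(95), dh(-4000), dh(-4000), dh(-4000), dh(-4000)),
    sex = "F", site = "A")
  admit <- c(dh(100, 12), dh(100, 12), dh(100, 12), dh(100, 12),
             dh(100, 12), dh(100, 12))
  disch <- c(dh(102, 11), dh(103, 11), dh(100, 22),
             dh(107, 12),          # exactly 7 days
             dh(106, 12),          # exactly 6 days
             dh(103, 11))
  admissions <- data.frame(
    patient_id = sprintf("q%d", 1:6), admit_time = admit,
    discharge_time = disch, death_time = NA_real_)
  # q6 readmitted exactly 30 days after discharge
  admissions <- rbind(admissions, data.frame(
    patient_id = "q6", admit_time = dh(103, 11) + 30 * DAY,
    discharge_time = dh(103, 11) + 30 * DAY + 600, death_time = NA_real_))
  events <- data.frame(
    patient_id = c("q4", "q5", "q6"),
    time = c(dh(102, 9),        # day 2 of stay, after prediction time
             dh(102, 9),
             dh(100, 20)),      # between admission and midnight
    code = "LAB/GLU",
    value = c(2.9, 3.0, 2.9))
  timelineSet(persons, events, admissions)
}

# small cached synthetic population (built once per test run)
small_pop <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthConfig(n_patients_per_site = 300L)
      cache <<- generateStudyData(cfg, seed = 99)
    }
    cache
  }
})

# brute-force O(n^2) AUROC oracle: exhaustive positive-negative pairs
pair_auroc <- function(score, label) {
  pos <- score[label == 1]; neg <- score[label == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}
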