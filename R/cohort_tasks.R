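# Inpatient cohort construction, the eight clinical prediction tasks, and
# patient-level data splits. Lab thresholds are compared strictly as
# printed in their clinical definitions (boundary values do not fire).

.TASKS <- list(
  mortality = list(kind = "mortality"),
  long_los = list(kind = "los", min_days = 7),
  readmission_30d = list(kind = "readmission", window_days = 30),
  hypoglycemia = list(kind = "lab", code = "LAB/GLU", threshold = 3,
                      direction = "lt"),
  hyponatremia = list(kind = "lab", code = "LAB/NA", threshold = 125,
                      direction = "lt"),
  hyperkalemia = list(kind = "lab", code = "LAB/K", threshold = 7,
                      direction = "gt"),
  thrombocytopenia = list(kind = "lab", code = "LAB/PLT", threshold = 50,
                          direction = "lt"),
  anemia = list(kind = "lab", code = "LAB/HGB", threshold = 70,
                direction = "lt"))

#' The eight clinical prediction tasks
#'
#' `taskNames()` lists the canonical task names; `taskSpec()` returns one
#' task's specification: in-hospital mortality, long length of stay (at
#' least 7 days), 30-day readmission, and five abnormal-lab tasks with
#' strict thresholds (serum glucose < 3 mmol/L, sodium < 125 mmol/L,
#' potassium > 7 mmol/L, platelets < 50 x10^9/L, hemoglobin < 70 g/L).
#' Prediction time is midnight closing the admission day, except 30-day
#' readmission which predicts at midnight closing the discharge day; the
#' outcome window runs to discharge (readmission: 30 days post-discharge).
#'
#' @param name a task name from `taskNames()`.
#' @return `taskSpec()`: a list with `name`, `kind`, and for lab tasks
#'   `code`, `threshold`, `direction`; `prediction_time_rule` and
#'   `window_rule` fields describe the timing conventions.
#' @export
taskNames <- function() names(.TASKS)

#' @rdname taskNames
#' @export
taskSpec <- function(name) {
  if (!name %in% names(.TASKS)) stop("unknown task name: ", name)
  spec <- .TASKS[[name]]
  spec$name <- name
  spec$prediction_time_rule <- if (spec$kind == "readmission")
    "discharge-midnight" else "admission-midnight"
  spec$window_rule <- if (spec$kind == "readmission")
    "30-days-post-discharge" else "until-discharge"
  spec
}

#' Build the inpatient cohort
#'
#' Applies the eligibility rules to every admission and selects exactly one
#' admission per remaining patient, uniformly at random with the given
#' seed: admissions below the site's minimum age at admission are removed,
#' as are admissions in which death or discharge occurred before the
#' earliest prediction time (midnight closing the admission day).
#'
#' @param timelines a [TimelineSet-class].
#' @param minAgeDays minimum age at admission in days; either a single
#'   value or a named vector keyed by site (e.g. `c(A = 28, B = 6570)`).
#' @param seed seed for the one-admission-per-patient sampling.
#' @return data.frame with columns `patient_id`, `admission_idx` (index
#'   into the patient's time-ordered admissions), `admit_time`,
#'   `discharge_time`, `death_time`, `site`.
#' @export
buildInpatientCohort <- function(timelines, minAgeDays = 28, seed = 1L) {
  stopifnot(is(timelines, "TimelineSet"))
  adm <- admissions(timelines)
  per <- persons(timelines)
  if (!nrow(adm)) {
    return(data.frame(patient_id = character(), admission_idx = integer(),
                      admit_time = numeric(), discharge_time = numeric(),
                      death_time = numeric(), site = character()))
  }
  d <- merge(adm, per[, c("patient_id", "birth_date", "site")],
             by = "patient_id", sort = FALSE)
  d <- d[order(d$patient_id, d$admit_time, method = "radix"), ]
  d$admission_idx <- stats::ave(seq_len(nrow(d)), d$patient_id,
                                FUN = seq_along)
  floor_days <- if (is.null(names(minAgeDays))) {
    rep(minAgeDays[1], nrow(d))
  } else {
    unname(minAgeDays[d$site])
  }
  age_days <- (d$admit_time - d$birth_date) / MINUTES_PER_DAY
  d <- d[age_days >= floor_days, , drop = FALSE]
  pred <- midnightAfter(d$admit_time)
  ended_early <- (!is.na(d$discharge_time) & d$discharge_time < pred) |
    (!is.na(d$death_time) & d$death_time < pred)
  d <- d[!ended_early, , drop = FALSE]
  if (!nrow(d)) {
    return(data.frame(patient_id = character(), admission_idx = integer(),
                      admit_time = numeric(), discharge_time = numeric(),
                      death_time = numeric(), site = character()))
  }
  .run_seeded(seed, {
    # uniform pick among each patient's eligible admissions, stable order
    d <- d[order(d$patient_id, d$admission_idx, method = "radix"), ]
    pick <- unlist(lapply(split(seq_len(nrow(d)), d$patient_id), function(ix) {
      if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)]
    }), use.names = FALSE)
    d <- d[sort(pick), c("patient_id", "admission_idx", "admit_time",
                         "discharge_time", "death_time", "site")]
    rownames(d) <- NULL
    d
  })
}

#' Label a task over the cohort
#'
#' Produces one labeled example per cohort admission for the given task,
#' applying the task's prediction-time rule, outcome window, and
#' exclusions. The prediction time is midnight closing the admission day
#' (readmission: midnight closing the discharge day). The label is 1 iff
#' the outcome occurs between the prediction time and discharge (for
#' readmission: within 30 days after discharge). Admissions in which the
#' outcome occurred before the prediction time are excluded from the task;
#' for readmission, admissions ending in in-hospital death are excluded
#' because death precedes the prediction time. Lab labels fire on the
#' first qualifying value at or after admission (strict threshold
#' comparison); readmission is ascertained against any later admission of
#' the same patient, whether or not that admission was itself selected for
#' the cohort.
#'
#' @param cohort data.frame from [buildInpatientCohort()].
#' @param task a task spec from [taskSpec()] (or a task name).
#' @param timelines the [TimelineSet-class] the cohort was built from.
#' @return data.frame with columns `patient_id`, `admission_idx`, `task`,
#'   `prediction_time`, `label`, `site`.
#' @export
labelTask <- function(cohort, task, timelines) {
  if (is.character(task)) task <- taskSpec(task)
  stopifnot(is(timelines, "TimelineSet"))
  empty <- data.frame(patient_id = character(), admission_idx = integer(),
                      task = character(), prediction_time = numeric(),
                      label = integer(), site = character())
  if (!nrow(cohort)) return(empty)
  n <- nrow(cohort)
  pred_adm <- midnightAfter(cohort$admit_time)
  disc <- cohort$discharge_time
  keep <- rep(TRUE, n)
  label <- integer(n)
  pt <- pred_adm

  if (task$kind == "readmission") {
    adm <- admissions(timelines)
    by_pat <- split(adm$admit_time, adm$patient_id)
    pred <- midnightAfter(disc)
    pt <- pred
    keep <- !is.na(disc) &
      !(!is.na(cohort$death_time) & cohort$death_time < pred)
    for (i in which(keep)) {
      later <- by_pat[[cohort$patient_id[i]]]
      later <- later[later > disc[i]]
      if (length(later) && any(later <= pred[i])) { keep[i] <- FALSE; next }
      label[i] <- as.integer(length(later) > 0 &&
        any(later <= disc[i] + task$window_days * MINUTES_PER_DAY))
    }
  } else if (task$kind == "mortality") {
    label <- as.integer(!is.na(cohort$death_time) &
                          (is.na(disc) | cohort$death_time <= disc))
  } else if (task$kind == "los") {
    keep <- !is.na(disc)
    label <- as.integer(!is.na(disc) &
                          (disc - cohort$admit_time) >=
                          task$min_days * MINUTES_PER_DAY)
  } else {  # lab: first qualifying crossing at or after admission
    ev <- events(timelines)
    sel <- ev$code == task$code & !is.na(ev$value)
    sel <- if (task$direction == "lt") sel & ev$value < task$threshold
           else sel & ev$value > task$threshold
    cr <- ev[sel, c("patient_id", "time")]
    by_pat <- split(cr$time, cr$patient_id)
    for (i in seq_len(n)) {
      tt <- by_pat[[cohort$patient_id[i]]]
      if (is.null(tt)) next
      tt <- tt[tt >= cohort$admit_time[i] & (is.na(disc[i]) | tt <= disc[i])]
      if (!length(tt)) next
      tc <- min(tt)
      if (tc < pred_adm[i]) keep[i] <- FALSE else label[i] <- 1L
    }
  }

  if (!any(keep)) return(empty)
  res <- data.frame(patient_id = cohort$patient_id[keep],
                    admission_idx = cohort$admission_idx[keep],
                    task = task$name, prediction_time = pt[keep],
                    label = label[keep], site = cohort$site[keep])
  rownames(res) <- NULL
  res
}

#' Label all eight tasks
#'
#' @inheritParams labelTask
#' @return row-bound data.frame of [labelTask()] results for every task.
#' @export
labelAllTasks <- function(cohort, timelines) {
  do.call(rbind, lapply(taskNames(), function(tn)
    labelTask(cohort, taskSpec(tn), timelines)))
}

#' Global 70/15/15 patient splits
#'
#' Partitions patients into train/validation/test folds in a 70/15/15
#' ratio by patient (never by admission), using largest-remainder rounding
#' (remainder ties broken in fold order train, valid, test) and a seeded
#' permutation.
#'
#' @param patientIds character vector of patient ids.
#' @param seed RNG seed.
#' @param props fold proportions (must sum to 1).
#' @return data.frame with columns `patient_id`, `fold` (train/valid/test).
#' @export
makeGlobalSplits <- function(patientIds, seed = 1L,
                             props = c(train = 0.7, valid = 0.15, test = 0.15)) {
  patientIds <- unique(as.character(patientIds))
  n <- length(patientIds)
  if (n < 10L) stop("need at least 10 patients to split")
  stopifnot(abs(sum(props) - 1) < 1e-9)
  quota <- n * props
  base <- floor(quota)
  rem <- quota - base
  left <- n - sum(base)
  if (left > 0) {
    give <- order(-rem, seq_along(rem))[seq_len(left)]  # largest remainder
    base[give] <- base[give] + 1
  }
  .run_seeded(seed, {
    perm <- sample(patientIds)
    fold <- rep(names(props), times = base)
    data.frame(patient_id = perm, fold = fold)[order(perm, method = "radix"), ] |>
      (\(d) { rownames(d) <- NULL; d })()
  })
}

#' Derive per-task splits from the global assignment
#'
#' Each labeled example inherits its patient's global fold, so task folds
#' are subsets of the global folds and no patient appears in two folds.
#'
#' @param examples labeled examples from [labelTask()]/[labelAllTasks()].
#' @param global data.frame from [makeGlobalSplits()].
#' @return `examples` with a `fold` column appended.
#' @export
deriveTaskSplits <- function(examples, global) {
  missing <- setdiff(examples$patient_id, global$patient_id)
  if (length(missing)) {
    stop("examples reference patients absent from the global split, e.g. ",
         missing[1])
  }
  fold <- global$fold[match(examples$patient_id, global$patient_id)]
  out <- examples
  out$fold <- fold
  out
}
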