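# OMOP-lite timeline store: a 3-table dialect (person, event, admission)
# sufficient for code-sequence modelling. Full OMOP CDM is out of scope.

MINUTES_PER_DAY <- 1440L

#' Timestamp helpers
#'
#' Timestamps are stored throughout the package as numeric minutes from the
#' Unix epoch (UTC), which makes calendar-day arithmetic exact:
#' `dayStart()` floors to 00:00 of the timestamp's calendar day and
#' `midnightAfter()` returns 00:00 of the following calendar day (the
#' "midnight on the day of" prediction-time convention — the midnight that
#' closes the day containing `t`).
#'
#' @param x ISO-8601 strings, `POSIXct`, or `Date` (for [toEpochMinutes()]);
#'   epoch minutes otherwise.
#' @param t numeric epoch minutes.
#' @return epoch minutes ([toEpochMinutes()], [dayStart()],
#'   [midnightAfter()]) or ISO-8601 strings ([fromEpochMinutes()]).
#' @name timestamps
NULL

#' @rdname timestamps
#' @export
toEpochMinutes <- function(x) {
  if (inherits(x, "POSIXct")) return(as.numeric(x) / 60)
  if (inherits(x, "Date")) return(as.numeric(x) * MINUTES_PER_DAY)
  if (is.numeric(x)) return(as.numeric(x))
  x <- as.character(x)
  out <- rep(NA_real_, length(x))
  todo <- !is.na(x) & nzchar(x)
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d")) {
    if (!any(todo)) break
    p <- as.POSIXct(strptime(x[todo], fmt, tz = "UTC"))
    hit <- !is.na(p)
    out[which(todo)[hit]] <- as.numeric(p[hit]) / 60
    todo[todo] <- !hit
  }
  out
}

#' @rdname timestamps
#' @export
fromEpochMinutes <- function(t) {
  out <- rep(NA_character_, length(t))
  ok <- !is.na(t)
  out[ok] <- format(as.POSIXct(round(t[ok]) * 60, origin = "1970-01-01",
                               tz = "UTC"),
                    "%Y-%m-%dT%H:%M:%S")
  out
}

#' @rdname timestamps
#' @export
dayStart <- function(t) floor(t / MINUTES_PER_DAY) * MINUTES_PER_DAY

#' @rdname timestamps
#' @export
midnightAfter <- function(t) dayStart(t) + MINUTES_PER_DAY

#' Construct a TimelineSet
#'
#' Assembles and validates a [TimelineSet-class] from its three component
#' tables. Events are sorted by patient, then time, stable in the input
#' order within ties. Timestamps may be given as ISO-8601 strings or epoch
#' minutes.
#'
#' @param persons data.frame: `patient_id`, `birth_date`, `sex`, `site`.
#' @param events data.frame: `patient_id`, `time`, `code`, `value`.
#' @param admissions data.frame: `patient_id`, `admit_time`,
#'   `discharge_time`, `death_time`.
#' @return a [TimelineSet-class].
#' @export
timelineSet <- function(persons,
                        events = data.frame(patient_id = character(),
                                            time = numeric(),
                                            code = character(),
                                            value = numeric()),
                        admissions = data.frame(patient_id = character(),
                                                admit_time = numeric(),
                                                discharge_time = numeric(),
                                                death_time = numeric())) {
  persons <- as.data.frame(persons, stringsAsFactors = FALSE)
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  admissions <- as.data.frame(admissions, stringsAsFactors = FALSE)
  persons$patient_id <- as.character(persons$patient_id)
  persons$birth_date <- toEpochMinutes(persons$birth_date)
  if (nrow(events)) {
    events$patient_id <- as.character(events$patient_id)
    events$time <- toEpochMinutes(events$time)
    events$value <- as.numeric(events$value)
    o <- order(events$patient_id, events$time, method = "radix")  # stable
    events <- events[o, c("patient_id", "time", "code", "value")]
    rownames(events) <- NULL
  } else {
    events <- data.frame(patient_id = character(), time = numeric(),
                         code = character(), value = numeric())
  }
  if (nrow(admissions)) {
    admissions$patient_id <- as.character(admissions$patient_id)
    for (cc in c("admit_time", "discharge_time", "death_time")) {
      admissions[[cc]] <- toEpochMinutes(admissions[[cc]])
    }
    o <- order(admissions$patient_id, admissions$admit_time, method = "radix")
    admissions <- admissions[o, c("patient_id", "admit_time",
                                  "discharge_time", "death_time")]
    rownames(admissions) <- NULL
  } else {
    admissions <- data.frame(patient_id = character(), admit_time = numeric(),
                             discharge_time = numeric(), death_time = numeric())
  }
  persons <- persons[order(persons$patient_id, method = "radix"),
                     c("patient_id", "birth_date", "sex", "site")]
  rownames(persons) <- NULL
  new("TimelineSet", persons = persons, events = events,
      admissions = admissions)
}

.required_cols <- list(
  person = c("patient_id", "birth_date", "sex", "site"),
  event = c("patient_id", "time", "code", "value"),
  admission = c("patient_id", "admit_time", "discharge_time", "death_time"))

.read_table <- function(path, what) {
  f <- file.path(path, paste0(what, ".csv"))
  if (!file.exists(f)) stop("missing table file: ", f)
  d <- as.data.frame(data.table::fread(f, na.strings = c("", "NA"),
                                       colClasses = "character"))
  missing <- setdiff(.required_cols[[what]], names(d))
  if (length(missing)) {
    stop("schema error in ", what, ".csv: missing column ",
         paste(missing, collapse = ", "))
  }
  d
}

.parse_time_col <- function(x, table, col) {
  given <- !is.na(x) & nzchar(as.character(x))
  out <- toEpochMinutes(x)
  bad <- which(given & is.na(out))
  if (length(bad)) {
    stop("unparseable timestamp in ", table, ".csv column ", col,
         " at row ", bad[1])
  }
  out
}

#' Read an OMOP-lite directory
#'
#' Reads `person.csv`, `event.csv` and `admission.csv` from `path` into a
#' [TimelineSet-class]. Timestamps must be ISO-8601; events are returned
#' time-sorted within patient (stable in file order within ties). A missing
#' required column raises a schema error naming the column; an unparseable
#' timestamp raises an error naming the row.
#'
#' @param path directory containing the three tables.
#' @return a [TimelineSet-class].
#' @seealso [writeOmopLite()]
#' @export
readOmopLite <- function(path) {
  per <- .read_table(path, "person")
  ev <- .read_table(path, "event")
  adm <- .read_table(path, "admission")
  per$birth_date <- .parse_time_col(per$birth_date, "person", "birth_date")
  ev$time <- .parse_time_col(ev$time, "event", "time")
  for (cc in c("admit_time", "discharge_time", "death_time")) {
    adm[[cc]] <- .parse_time_col(adm[[cc]], "admission", cc)
  }
  timelineSet(per, ev, adm)
}

#' Write an OMOP-lite directory
#'
#' Writes the three tables of a [TimelineSet-class] as CSV with ISO-8601
#' timestamps, deterministic column order and deterministic row order
#' (patient, then time, then input order), so identical inputs produce
#' byte-identical files and [readOmopLite()] round-trips losslessly on the
#' canonical column set.
#'
#' @param timelines a [TimelineSet-class].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
writeOmopLite <- function(timelines, path) {
  stopifnot(is(timelines, "TimelineSet"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create output directory: ", path)
  per <- persons(timelines)
  per$birth_date <- fromEpochMinutes(per$birth_date)
  ev <- events(timelines)
  ev$time <- fromEpochMinutes(ev$time)
  adm <- admissions(timelines)
  for (cc in c("admit_time", "discharge_time", "death_time")) {
    adm[[cc]] <- fromEpochMinutes(adm[[cc]])
  }
  data.table::fwrite(per, file.path(path, "person.csv"), na = "")
  data.table::fwrite(ev, file.path(path, "event.csv"), na = "")
  data.table::fwrite(adm, file.path(path, "admission.csv"), na = "")
  invisible(path)
}

#' Slice patient history at a prediction time
#'
#' Returns a copy of the timeline set whose events are restricted to those
#' strictly before `t` (events at or after the prediction time are excluded
#' to prevent label leakage). Demographics and admission metadata are
#' retained; the input object is not modified.
#'
#' @param object a [TimelineSet-class].
#' @param t prediction time, epoch minutes (single value).
#' @param patientId optional: restrict to one patient's timeline.
#' @return a [TimelineSet-class].
#' @export
setGeneric("sliceHistory", function(object, t, patientId = NULL)
  standardGeneric("sliceHistory"))

#' @rdname sliceHistory
#' @export
setMethod("sliceHistory", "TimelineSet", function(object, t, patientId = NULL) {
  stopifnot(length(t) == 1, is.finite(t))
  ev <- events(object)
  keep <- ev$time < t
  per <- persons(object)
  adm <- admissions(object)
  if (!is.null(patientId)) {
    keep <- keep & ev$patient_id == patientId
    per <- per[per$patient_id == patientId, , drop = FALSE]
    adm <- adm[adm$patient_id == patientId, , drop = FALSE]
    rownames(per) <- rownames(adm) <- NULL
  }
  ev <- ev[keep, , drop = FALSE]
  rownames(ev) <- NULL
  new("TimelineSet", persons = per, events = ev, admissions = adm)
})
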