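test_that("OMOP-lite round-trip is lossless and deterministic", {
  tl <- tiny_timelines()
  d1 <- file.path(tempdir(), "omop1")
  d2 <- file.path(tempdir(), "omop2")
  writeOmopLite(tl, d1)
  tl2 <- readOmopLite(d1)
  expect_equal(persons(tl2), persons(tl))
  expect_equal(events(tl2), events(tl))
  expect_equal(admissions(tl2), admissions(tl))
  writeOmopLite(tl2, d2)
  for (f in c("person.csv", "event.csv", "admission.csv")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})

test_that("round-trip is lossless for generated synthetic populations", {
  for (sd in c(4, 5)) {
    cfg <- synthConfig(n_patients_per_site = 60L)
    tl <- generateSitePopulation(cfg, "A", seed = sd)
    d <- file.path(tempdir(), paste0("omop_seed", sd))
    writeOmopLite(tl, d)
    tl2 <- readOmopLite(d)
    expect_equal(events(tl2), events(tl))
    expect_equal(admissions(tl2), admissions(tl))
    expect_equal(persons(tl2), persons(tl))
  }
})

test_that("persons with no events yield empty timelines", {
  d <- file.path(tempdir(), "omop_empty")
  dir.create(d, showWarnings = FALSE)
  writeLines("patient_id,birth_date,sex,site\na,1970-01-01,F,X\nb,1970-01-01,M,X\nc,1970-01-01,F,X",
             file.path(d, "person.csv"))
  writeLines("patient_id,time,code,value", file.path(d, "event.csv"))
  writeLines("patient_id,admit_time,discharge_time,death_time",
             file.path(d, "admission.csv"))
  tl <- readOmopLite(d)
  expect_equal(nrow(persons(tl)), 3L)
  expect_equal(nrow(events(tl)), 0L)
})

test_that("events out of order on disk are returned time-sorted, stable in ties", {
  d <- file.path(tempdir(), "omop_oo")
  dir.create(d, showWarnings = FALSE)
  writeLines(c("patient_id,birth_date,sex,site",
               "a,1970-01-01,F,X", "b,1970-01-01,M,X"),
             file.path(d, "person.csv"))
  writeLines(c("patient_id,time,code,value",
               "a,2020-01-03T00:00:00,C3,",
               "a,2020-01-01T00:00:00,C1,",
               "b,2020-01-02T00:00:00,B1,",
               "a,2020-01-02T00:00:00,TIE_FIRST,",
               "a,2020-01-02T00:00:00,TIE_SECOND,"),
             file.path(d, "event.csv"))
  writeLines("patient_id,admit_time,discharge_time,death_time",
             file.path(d, "admission.csv"))
  tl <- readOmopLite(d)
  ev_a <- events(tl)[events(tl)$patient_id == "a", ]
  expect_equal(ev_a$code, c("C1", "TIE_FIRST", "TIE_SECOND", "C3"))
  expect_false(is.unsorted(ev_a$time))
})

test_that("schema and timestamp errors are informative", {
  d <- file.path(tempdir(), "omop_bad")
  dir.create(d, showWarnings = FALSE)
  writeLines("patient_id,birth_date,sex", file.path(d, "person.csv"))
  writeLines("patient_id,time,code,value", file.path(d, "event.csv"))
  writeLines("patient_id,admit_time,discharge_time,death_time",
             file.path(d, "admission.csv"))
  expect_error(readOmopLite(d), "site")
  writeLines(c("patient_id,birth_date,sex,site", "a,1970-01-01,F,X"),
             file.path(d, "person.csv"))
  writeLines(c("patient_id,time,code,value",
               "a,2020-01-01T00:00:00,C1,",
               "a,not-a-time,C2,"),
             file.path(d, "event.csv"))
  expect_error(readOmopLite(d), "row 2")
})

test_that("sliceHistory keeps strictly-before events and admission metadata", {
  tl <- tiny_timelines()
  # p1 has events at 09:00 on days 1, 2, 3; slice at day-3 midnight
  sl <- sliceHistory(tl, dh(3), patientId = "p1")
  expect_equal(nrow(events(sl)), 2L)
  expect_true(all(events(sl)$time < dh(3)))
  expect_equal(nrow(admissions(sl)), 1L)
  # before first event -> empty; after last -> identical
  expect_equal(nrow(events(sliceHistory(tl, dh(0), patientId = "p1"))), 0L)
  expect_equal(nrow(events(sliceHistory(tl, dh(10), patientId = "p1"))), 3L)
  # original unmodified
  expect_equal(nrow(events(tl)), 5L)
})

test_that("slice at t plus the remainder reproduces the event multiset", {
  tl <- small_pop()
  t_cut <- stats::median(events(tl)$time)
  before <- events(sliceHistory(tl, t_cut))
  after <- events(tl)[events(tl)$time >= t_cut, ]
  combined <- rbind(before, after)
  combined <- combined[order(combined$patient_id, combined$time,
                             combined$code, method = "radix"), ]
  orig <- events(tl)
  orig <- orig[order(orig$patient_id, orig$time, orig$code,
                     method = "radix"), ]
  rownames(combined) <- rownames(orig) <- NULL
  expect_equal(combined, orig)
})

test_that("writing zero timelines produces valid empty tables", {
  tl <- timelineSet(data.frame(patient_id = character(),
                               birth_date = numeric(), sex = character(),
                               site = character()))
  d <- file.path(tempdir(), "omop_zero")
  writeOmopLite(tl, d)
  tl2 <- readOmopLite(d)
  expect_equal(nrow(persons(tl2)), 0L)
  expect_equal(nrow(events(tl2)), 0L)
})
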