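# A deliberately tiny plan so the full pipeline runs in seconds; the
# realistically sized benchmark lives in the acceptance suite.
tiny_plan <- function(seed = 1L) {
  experimentPlan(
    synth = synthConfig(n_patients_per_site = 250L),
    fm = fmConfig(n_layers = 1L, hidden_size = 16L, n_heads = 2L,
                  attn_window = 8L, max_seq_len = 32L,
                  lr_candidates = 1e-3, batch_tokens = 128L,
                  max_steps = 40L, eval_every = 20L, patience = 30L,
                  representation = "mean"),
    seed = seed,
    fractions = c(0.5, 1),
    fewshot = fewShotDesign(kGrid = 4L, iterations = 1L),
    fewshotTasks = "long_los",
    bootstrapB = 150L)
}

run_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- runOverallExperiment(tiny_plan(), compare = TRUE)
    }
    cache
  }
})

test_that("the overall experiment produces coherent arm-by-task metrics", {
  run <- run_cache()
  m <- run$metrics
  expect_true(all(c("site", "model", "task", "auroc", "ece") %in% names(m)))
  expect_setequal(unique(m$model),
                  c("gbm", "fm_local", "fm_external", "fm_external_cp"))
  expect_true(all(m$auroc >= 0 & m$auroc <= 1))
  expect_true(all(m$ece >= 0 & m$ece <= 1))
  # every arm is evaluated on the same task set within a site
  for (site in c("A", "B")) {
    counts <- table(m$model[m$site == site])
    expect_length(unique(as.integer(counts)), 1L)
  }
  expect_true(length(run$comparisons) > 0)
  for (cr in run$comparisons) expect_s4_class(cr, "ComparisonResult")
})

test_that("checkpoint provenance records arms and pretraining corpora", {
  run <- run_cache()
  ck <- run$checkpoints
  expect_equal(provenance(ck$A)$kind, "from_scratch")
  expect_equal(provenance(ck$ApB)$kind, "continued")
  expect_equal(provenance(ck$ApB)$parent_site, "A")
  expect_identical(vocabCodes(fmVocabulary(ck$ApB)),
                   vocabCodes(fmVocabulary(ck$A)))
  expect_true(all(provenance(ck$B)$pretrain_patients %in%
                    run$study$B$trainPatients))
})

test_that("the leakage audit passes and catches planted leakage", {
  run <- run_cache()
  expect_true(auditLeakage(run))
  bad <- run
  bad$checkpoints$A@provenance$pretrain_patients <-
    c(bad$checkpoints$A@provenance$pretrain_patients,
      run$study$B$testPatients[1])
  expect_error(auditLeakage(bad), "leakage")
})

test_that("few-shot pretraining exclusion is enforced end to end", {
  run <- run_cache()
  plan <- tiny_plan()
  exB <- run$study$B$examples
  excl <- unique(exB$patient_id[exB$fold == "train"])
  ck_fs <- ehrfm:::.continue_site(run$checkpoints$A, run$study, "B", plan,
                                  17, exclude = excl)
  expect_true(auditLeakage(run, fewshotCheckpoint = ck_fs,
                           fewshotSite = "B"))
  expect_length(intersect(provenance(ck_fs)$pretrain_patients, excl), 0)
  # a checkpoint adapted on the full corpus fails this audit
  expect_error(auditLeakage(run, fewshotCheckpoint = run$checkpoints$ApB,
                            fewshotSite = "B"),
               "task-train")
})

test_that("the from-scratch subsample arm at fraction 1 is the local model", {
  run <- run_cache()
  plan <- tiny_plan()
  sub <- runSubsampleExperiment(plan, run$study, run$checkpoints$A,
                                site = "B", tasks = c("long_los", "anemia"),
                                includeScratch = TRUE,
                                localFull = run$checkpoints$B,
                                continuedFull = run$checkpoints$ApB)
  m <- run$metrics
  for (tn in c("long_los", "anemia")) {
    a_sub <- sub$auroc[sub$arm == "scratch" & sub$fraction == 1 &
                         sub$task == tn]
    a_loc <- m$auroc[m$site == "B" & m$model == "fm_local" & m$task == tn]
    if (length(a_sub) && length(a_loc)) {
      expect_equal(a_sub, a_loc, tolerance = 1e-12)
    }
  }
  expect_true(all(c("arm", "fraction", "task", "auroc") %in% names(sub)))
  expect_s3_class(attr(sub, "mean"), "data.frame")
})

test_that("the pipeline is deterministic end to end", {
  plan <- tiny_plan(seed = 3L)
  r1 <- runOverallExperiment(plan, compare = FALSE, tasks = "long_los")
  r2 <- runOverallExperiment(plan, compare = FALSE, tasks = "long_los")
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$manifest$config_hash, r2$manifest$config_hash)
})

test_that("run manifests hash the configuration stably", {
  p1 <- tiny_plan(seed = 1L)
  expect_identical(runManifest(p1)$config_hash, runManifest(p1)$config_hash)
  expect_false(runManifest(p1)$config_hash ==
                 runManifest(tiny_plan(seed = 2L))$config_hash)
})

test_that("reports render deterministically from result tables", {
  d <- file.path(tempdir(), "results_report")
  dir.create(d, showWarnings = FALSE)
  utils::write.csv(data.frame(site = "B", model = "gbm", task = "anemia",
                              auroc = 0.7123, ece = 0.02),
                   file.path(d, "metrics.csv"), row.names = FALSE)
  f1 <- reportResults(d, out = file.path(d, "s1.md"))
  f2 <- reportResults(d, out = file.path(d, "s2.md"))
  expect_identical(readLines(f1), readLines(f2))
  expect_true(any(grepl("metrics", readLines(f1))))
  # empty results directory: headers only
  d0 <- file.path(tempdir(), "results_empty")
  dir.create(d0, showWarnings = FALSE)
  f0 <- reportResults(d0, out = file.path(d0, "s.md"))
  expect_equal(readLines(f0)[1], "# Benchmark report")
})
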