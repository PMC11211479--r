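# End-to-end orchestration of the three experiment families on synthetic
# two-site data: overall comparison + cross-site ablation, few-shot label
# efficiency, and pretraining-subsample curves. Every pretraining corpus is
# drawn from global train folds only; an automated audit checks that no
# test-fold patient leaks into pretraining or tuning.

#' Experiment plan for the two-site benchmark
#'
#' Bundles the synthetic-data config, the foundation-model config, and the
#' experiment settings (few-shot design, subsample fractions, bootstrap
#' replicates) into one reproducible plan. Defaults define the package's
#' desk-scale benchmark: 2 sites x 1500 patients, a 2-layer hidden-32
#' transformer, few-shot at k in {16, 64} on the four most prevalent
#' tasks, and subsample fractions {0.05, 0.2, 1}.
#'
#' @param synth a `synth_config` from [synthConfig()].
#' @param fm an `fm_config` from [fmConfig()].
#' @param seed master seed; stage seeds derive from it.
#' @param fractions pretraining subsample fractions in (0, 1].
#' @param fewshot a [fewShotDesign()].
#' @param fewshotTasks tasks used in the few-shot grid (tasks need enough
#'   positives in the training fold to fill balanced draws).
#' @param minAgeDays named vector of per-site age floors (days).
#' @param bootstrapB hierarchical-bootstrap replicates for comparisons.
#' @param vocabK vocabulary capacity for each foundation model.
#' @return list of class `experiment_plan`.
#' @export
experimentPlan <- function(synth = synthConfig(n_patients_per_site = 1500L),
                           fm = fmConfig(hidden_size = 32L, n_heads = 4L,
                                         attn_window = 16L, max_seq_len = 64L,
                                         lr_candidates = 1e-3,
                                         batch_tokens = 320L,
                                         max_steps = 300L, eval_every = 50L,
                                         patience = 200L,
                                         representation = "mean"),
                           seed = 1L,
                           fractions = c(0.05, 0.2, 1),
                           fewshot = fewShotDesign(kGrid = c(16L, 64L),
                                                   iterations = 3L),
                           fewshotTasks = c("long_los", "mortality",
                                            "hypoglycemia",
                                            "thrombocytopenia"),
                           minAgeDays = c(A = 28, B = 18 * 365),
                           bootstrapB = 500L,
                           vocabK = 128L) {
  stopifnot(all(fractions > 0), all(fractions <= 1))
  structure(list(synth = synth, fm = fm, seed = as.integer(seed),
                 fractions = sort(unique(fractions)), fewshot = fewshot,
                 fewshotTasks = fewshotTasks, minAgeDays = minAgeDays,
                 bootstrapB = as.integer(bootstrapB),
                 vocabK = as.integer(vocabK)),
            class = "experiment_plan")
}

#' Lightweight run manifest
#'
#' Content hash of the plan (djb2 over its serialized form, mod 2^31) plus
#' the seed, for keying output directories and asserting that a re-run saw
#' identical inputs.
#'
#' @param plan an [experimentPlan()].
#' @return list with `config_hash`, `seed`, `created`.
#' @export
runManifest <- function(plan) {
  s <- paste(utils::capture.output(utils::str(plan, digits.d = 15,
                                              list.len = 1e6)),
             collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% (2^31 - 1)
  list(config_hash = sprintf("%08x", as.integer(h)), seed = plan$seed,
       created = "unversioned-run")
}

# derive stage seeds (kept below 2^31)
.stage_seed <- function(seed, stage) {
  (as.numeric(seed) * 7919 + stage * 104729) %% (2^31 - 1)
}

#' Prepare the two-site study data
#'
#' Generates both sites, builds cohorts, labels all eight tasks, makes the
#' global 70/15/15 patient splits and derives task splits, builds each
#' site's vocabulary from its own global training fold, and tokenizes the
#' per-fold pretraining corpora.
#'
#' @param plan an [experimentPlan()].
#' @param seed override of the plan seed.
#' @return list keyed by site, each with `timelines`, `cohort`, `examples`
#'   (labeled + fold column), `splits`, `vocab`, `corpus` (tokenized
#'   train/valid lists), `trainPatients`, `validPatients`, `testPatients`.
#' @export
prepareStudy <- function(plan, seed = plan$seed) {
  out <- list()
  for (sn in names(plan$synth$sites)) {
    tl <- generateSitePopulation(plan$synth, sn,
                                 seed = .stage_seed(seed, match(sn, c("A", "B"))))
    coh <- buildInpatientCohort(tl, minAgeDays = plan$minAgeDays[[sn]],
                                seed = .stage_seed(seed, 10))
    ex <- labelAllTasks(coh, tl)
    sp <- makeGlobalSplits(persons(tl)$patient_id,
                           seed = .stage_seed(seed, 20))
    ex <- deriveTaskSplits(ex, sp)
    folds <- split(sp$patient_id, sp$fold)
    vocab <- buildVocabulary(subsetPatients(tl, folds$train), K = plan$vocabK)
    corpus_tr <- tokenize(subsetPatients(tl, folds$train), vocab)
    corpus_va <- tokenize(subsetPatients(tl, folds$valid), vocab)
    out[[sn]] <- list(site = sn, timelines = tl, cohort = coh, examples = ex,
                      splits = sp, vocab = vocab,
                      corpus = list(train = corpus_tr, valid = corpus_va),
                      trainPatients = folds$train,
                      validPatients = folds$valid,
                      testPatients = folds$test)
  }
  out
}

# tokenized corpus restricted to a patient subset (keeps vocab attribute)
.corpus_subset <- function(corpus, patients) {
  keep <- intersect(names(corpus), patients)
  out <- corpus[keep]
  attr(out, "vocab_codes") <- attr(corpus, "vocab_codes")
  out
}

.pretrain_site <- function(study, site, plan, seed, exclude = character()) {
  s <- study[[site]]
  tr <- .corpus_subset(s$corpus$train, setdiff(names(s$corpus$train), exclude))
  ck <- pretrainFM(tr, s$corpus$valid, s$vocab, plan$fm, seed = seed,
                   site = site)
  ck@provenance$pretrain_patients <- names(tr)
  ck
}

.continue_site <- function(parent, study, site, plan, seed,
                           exclude = character(), frac = 1) {
  s <- study[[site]]
  # the adaptation corpus must be tokenized with the parent vocabulary
  tl_tr <- subsetPatients(s$timelines,
                          setdiff(s$trainPatients, exclude))
  corpus_tr <- tokenize(tl_tr, parent@vocabulary)
  if (frac < 1) {
    pats <- sort(names(corpus_tr))
    n_keep <- max(2L, floor(length(pats) * frac))
    keep <- .run_seeded(.stage_seed(seed, 33), sample(pats, n_keep))
    corpus_tr <- .corpus_subset(corpus_tr, keep)
  }
  corpus_va <- tokenize(subsetPatients(s$timelines, s$validPatients),
                        parent@vocabulary)
  ck <- continuePretrainFM(parent, corpus_tr, corpus_va, config = plan$fm,
                           seed = seed, site = site)
  ck@provenance$pretrain_patients <- union(parent@provenance$pretrain_patients,
                                           names(corpus_tr))
  ck@provenance$subsample_fraction <- frac
  ck
}

# per-task fold data.frames for one site
.task_folds <- function(study_site, task) {
  ex <- study_site$examples
  ex <- ex[ex$task == task, , drop = FALSE]
  lapply(c(train = "train", valid = "valid", test = "test"),
         function(f) ex[ex$fold == f, , drop = FALSE])
}

# one representation pass per (checkpoint, site): encode every unique
# (patient, prediction time) across all tasks, return a row-lookup closure
.rep_lookup <- function(ckpt, study_site) {
  ex <- study_site$examples
  key <- paste(ex$patient_id, ex$prediction_time)
  uniq <- ex[!duplicated(key), c("patient_id", "prediction_time")]
  reps <- extractRepresentations(ckpt, uniq, study_site$timelines)
  ukey <- paste(uniq$patient_id, uniq$prediction_time)
  function(df) {
    reps[match(paste(df$patient_id, df$prediction_time), ukey), ,
         drop = FALSE]
  }
}

# fit a linear probe on frozen representations for one task; returns test
# predictions (NULL when a fold is degenerate)
.probe_task <- function(lookup, study_site, task, seed) {
  f <- .task_folds(study_site, task)
  if (nrow(f$train) < 4 || length(unique(f$train$label)) < 2 ||
      length(unique(f$test$label)) < 2 || nrow(f$valid) < 2) return(NULL)
  head <- fitLinearHead(lookup(f$train), f$train$label,
                        lookup(f$valid), f$valid$label, seed = seed)
  list(p = predictHead(head, lookup(f$test)), label = f$test$label,
       head = head)
}

# fit the count-GBM baseline for one task; returns test predictions
.gbm_task <- function(study_site, task, seed) {
  f <- .task_folds(study_site, task)
  if (nrow(f$train) < 4 || length(unique(f$train$label)) < 2 ||
      length(unique(f$test$label)) < 2 || nrow(f$valid) < 2) return(NULL)
  tl <- study_site$timelines
  x_all <- countFeaturize(f$train, tl)
  code_cols <- setdiff(colnames(x_all), c("age_days", "sex_male"))
  seen <- code_cols[Matrix::colSums(x_all[, code_cols, drop = FALSE]) > 0]
  xtr <- x_all[, c(seen, "age_days", "sex_male"), drop = FALSE]
  xva <- countFeaturize(f$valid, tl, seen)
  xte <- countFeaturize(f$test, tl, seen)
  head <- fitGbmHead(xtr, f$train$label, xva, f$valid$label, seed = seed)
  list(p = predictHead(head, xte), label = f$test$label, head = head)
}

.metric_rows <- function(preds_by_task, site, model) {
  rows <- lapply(names(preds_by_task), function(tn) {
    pr <- preds_by_task[[tn]]
    if (is.null(pr)) return(NULL)
    data.frame(site = site, model = model, task = tn,
               auroc = auroc(pr$p, pr$label),
               ece = eceQuantile(pr$p, pr$label),
               n_test = length(pr$label))
  })
  do.call(rbind, rows)
}

.preds_frame <- function(preds_by_task) {
  do.call(rbind, lapply(names(preds_by_task), function(tn) {
    pr <- preds_by_task[[tn]]
    if (is.null(pr)) return(NULL)
    data.frame(task = tn, p = pr$p, label = pr$label)
  }))
}

#' Overall comparison and cross-site ablation
#'
#' Trains the plan's model arms — local count-GBMs, local foundation
#' models pretrained from scratch, the external foundation model from the
#' other site (off-the-shelf and with continued pretraining) — and
#' evaluates per-task AUROC and ECE of every arm on each site's test
#' fold, with hierarchical-bootstrap comparisons of each foundation-model
#' arm against the local GBM and the local FM.
#'
#' @param plan an [experimentPlan()].
#' @param study optional pre-built [prepareStudy()] result.
#' @param tasks tasks to evaluate (default all eight).
#' @param compare compute bootstrap comparisons (default TRUE).
#' @return list with `metrics` (data.frame site x model x task),
#'   `comparisons` (named list of [ComparisonResult-class]), `checkpoints`,
#'   `study`, and `manifest`.
#' @export
runOverallExperiment <- function(plan, study = NULL, tasks = taskNames(),
                                 compare = TRUE) {
  seed <- plan$seed
  if (is.null(study)) study <- prepareStudy(plan, seed)
  ck <- list()
  ck$A <- .pretrain_site(study, "A", plan, .stage_seed(seed, 101))
  ck$B <- .pretrain_site(study, "B", plan, .stage_seed(seed, 102))
  ck$ApB <- .continue_site(ck$A, study, "B", plan, .stage_seed(seed, 103))
  ck$BpA <- .continue_site(ck$B, study, "A", plan, .stage_seed(seed, 104))

  metrics <- list(); preds <- list()
  for (site in c("A", "B")) {
    ext <- if (site == "A") "B" else "A"
    arms <- list(gbm = NULL,
                 fm_local = ck[[site]],
                 fm_external = ck[[ext]],
                 fm_external_cp = ck[[paste0(ext, "p", site)]])
    for (an in names(arms)) {
      lk <- if (an != "gbm") .rep_lookup(arms[[an]], study[[site]])
      pb <- setNames(lapply(tasks, function(tn) {
        if (an == "gbm") .gbm_task(study[[site]], tn, .stage_seed(seed, 200))
        else .probe_task(lk, study[[site]], tn, .stage_seed(seed, 201))
      }), tasks)
      metrics[[paste(site, an)]] <- .metric_rows(pb, site, an)
      preds[[paste(site, an)]] <- .preds_frame(pb)
    }
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL

  comparisons <- list()
  if (compare && length(tasks) > 1) {
    for (site in c("A", "B")) {
      for (an in c("fm_external", "fm_external_cp")) {
        for (base in c("gbm", "fm_local")) {
          a <- preds[[paste(site, an)]]; b <- preds[[paste(site, base)]]
          if (is.null(a) || is.null(b)) next
          common <- intersect(unique(a$task), unique(b$task))
          a <- a[a$task %in% common, ]; b <- b[b$task %in% common, ]
          for (m in c("auroc", "ece")) {
            comparisons[[paste(site, an, "vs", base, m)]] <-
              hierarchicalBootstrapDiff(a, b, metric = m, B = plan$bootstrapB,
                                        seed = .stage_seed(seed, 300))
          }
        }
      }
    }
  }
  list(metrics = metrics, comparisons = comparisons, checkpoints = ck,
       preds = preds, study = study, manifest = runManifest(plan))
}

#' Pretraining-subsample experiment
#'
#' For each fraction of the target site's global training patients:
#' continue-pretrain the external foundation model on the subsample and
#' (optionally) pretrain a local model from scratch on it, then evaluate
#' linear probes on the fixed task test folds. Emits AUROC-vs-fraction
#' curves relative to the fully trained local model.
#'
#' @param plan an [experimentPlan()].
#' @param study a [prepareStudy()] result.
#' @param parent the external checkpoint to adapt (e.g. trained on site A).
#' @param site target site being subsampled (default "B").
#' @param tasks tasks to evaluate.
#' @param includeScratch also train from-scratch arms per fraction.
#' @param localFull optional precomputed full-data local checkpoint
#'   (fraction 1 scratch arm); reused instead of retraining.
#' @param continuedFull optional precomputed full continued checkpoint.
#' @return data.frame: `arm`, `fraction`, `task`, `auroc`, plus attribute
#'   `"mean"` with per-(arm, fraction) mean AUROC.
#' @export
runSubsampleExperiment <- function(plan, study, parent, site = "B",
                                   tasks = taskNames(),
                                   includeScratch = FALSE,
                                   localFull = NULL, continuedFull = NULL) {
  seed <- plan$seed
  rows <- list()
  eval_ck <- function(ckpt, arm, frac) {
    lk <- .rep_lookup(ckpt, study[[site]])
    for (tn in tasks) {
      pr <- .probe_task(lk, study[[site]], tn, .stage_seed(seed, 400))
      if (is.null(pr)) next
      rows[[length(rows) + 1L]] <<- data.frame(
        arm = arm, fraction = frac, task = tn,
        auroc = auroc(pr$p, pr$label))
    }
  }
  n_train <- length(study[[site]]$trainPatients)
  for (fr in plan$fractions) {
    if (fr * n_train < 10) {
      warning("fraction ", fr, " yields fewer than 10 patients; skipped")
      next
    }
    ckc <- if (fr == 1 && !is.null(continuedFull)) continuedFull
           else .continue_site(parent, study, site, plan,
                               .stage_seed(seed, 500 + round(1000 * fr)),
                               frac = fr)
    eval_ck(ckc, "continued", fr)
    if (includeScratch) {
      cks <- if (fr == 1 && !is.null(localFull)) localFull
      else {
        pats <- sort(study[[site]]$trainPatients)
        keep <- .run_seeded(.stage_seed(seed, 600 + round(1000 * fr)),
                            sample(pats, max(2L, floor(length(pats) * fr))))
        s <- study[[site]]
        tr <- .corpus_subset(s$corpus$train, keep)
        ck <- pretrainFM(tr, s$corpus$valid, s$vocab, plan$fm,
                         seed = .stage_seed(seed, 601 + round(1000 * fr)),
                         site = site)
        ck@provenance$pretrain_patients <- names(tr)
        ck
      }
      eval_ck(cks, "scratch", fr)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  mean_tbl <- stats::aggregate(auroc ~ arm + fraction, out, mean)
  attr(out, "mean") <- mean_tbl
  out
}

#' Few-shot experiment on the benchmark
#'
#' Builds the few-shot arms for a target site — linear probes on the
#' (leakage-clean) continued external foundation model vs the count-GBM
#' baseline — and runs the sampling grid. The continued checkpoint used
#' here is trained with every task-train patient removed from its
#' adaptation corpus.
#'
#' @param plan an [experimentPlan()].
#' @param study a [prepareStudy()] result.
#' @param fmCheckpoint the (exclusion-clean) checkpoint encoding features.
#' @param site target site.
#' @return list with `results` (per-cell), `summary` (per-cell means).
#' @export
runFewShotBenchmark <- function(plan, study, fmCheckpoint, site = "B") {
  s <- study[[site]]
  tl <- s$timelines
  lk <- .rep_lookup(fmCheckpoint, s)
  tasks <- list(); feat_fm <- list(); feat_cnt <- list()
  for (tn in plan$fewshotTasks) {
    f <- .task_folds(s, tn)
    if (sum(f$train$label == 1) < 1 || sum(f$train$label == 0) < 1) next
    tasks[[tn]] <- f
    feat_fm[[tn]] <- lapply(f, lk)
    x_all <- countFeaturize(f$train, tl)
    code_cols <- setdiff(colnames(x_all), c("age_days", "sex_male"))
    seen <- code_cols[Matrix::colSums(x_all[, code_cols, drop = FALSE]) > 0]
    feat_cnt[[tn]] <- list(
      train = x_all[, c(seen, "age_days", "sex_male"), drop = FALSE],
      valid = countFeaturize(f$valid, tl, seen),
      test = countFeaturize(f$test, tl, seen))
  }
  arms <- list(
    fm_plus = list(kind = "fm", feat = feat_fm),
    gbm = list(kind = "count", feat = feat_cnt))
  res <- runFewShotExperiment(arms, tasks, plan$fewshot)
  list(results = res, summary = summarizeFewShot(res))
}

#' Leakage audit
#'
#' Asserts the structural no-leakage guarantees of a benchmark run: no
#' test-fold patient of the evaluation site appears in any checkpoint's
#' pretraining corpus; task folds are patient-disjoint; a few-shot
#' checkpoint's adaptation corpus contains no task-train patient.
#'
#' @param run a [runOverallExperiment()] result (or compatible list with
#'   `checkpoints` and `study`).
#' @param fewshotCheckpoint optional few-shot checkpoint to audit, with
#'   the site it encodes features for.
#' @param fewshotSite site of the few-shot experiment.
#' @return TRUE invisibly on success; otherwise an error describing the
#'   first violation.
#' @export
auditLeakage <- function(run, fewshotCheckpoint = NULL, fewshotSite = "B") {
  study <- run$study
  test_pats <- unlist(lapply(study, `[[`, "testPatients"))
  valid_pats <- unlist(lapply(study, `[[`, "validPatients"))
  for (cn in names(run$checkpoints)) {
    pp <- run$checkpoints[[cn]]@provenance$pretrain_patients
    bad <- intersect(pp, test_pats)
    if (length(bad)) {
      stop("leakage: test patient ", bad[1], " in pretraining corpus of ", cn)
    }
    bad2 <- intersect(pp, valid_pats)
    if (length(bad2)) {
      stop("leakage: validation patient ", bad2[1],
           " in pretraining corpus of ", cn)
    }
  }
  for (sn in names(study)) {
    ex <- study[[sn]]$examples
    for (tn in unique(ex$task)) {
      e <- ex[ex$task == tn, ]
      by_fold <- split(e$patient_id, e$fold)
      pairs <- utils::combn(names(by_fold), 2, simplify = FALSE)
      for (pr in pairs) {
        if (length(intersect(by_fold[[pr[1]]], by_fold[[pr[2]]]))) {
          stop("leakage: patient in two folds for task ", tn, " at ", sn)
        }
      }
    }
  }
  if (!is.null(fewshotCheckpoint)) {
    ex <- study[[fewshotSite]]$examples
    task_train <- unique(ex$patient_id[ex$fold == "train"])
    # only the adaptation-corpus patients of the target site matter; the
    # parent's own-site corpus cannot contain them
    pp <- fewshotCheckpoint@provenance$pretrain_patients
    own <- intersect(pp, persons(study[[fewshotSite]]$timelines)$patient_id)
    bad <- intersect(own, task_train)
    if (length(bad)) {
      stop("leakage: few-shot pretraining saw task-train patient ", bad[1])
    }
  }
  invisible(TRUE)
}

#' Run the full directional benchmark once
#'
#' Executes the pipeline end-to-end for one seed and reports the three
#' directional indicators of the study: (a) continued pretraining improves
#' the external foundation model's mean test AUROC at the adaptation site;
#' (b) few-shot linear probes on the continued model beat the full-grid
#' count-GBM mean AUROC at small k; (c) continued pretraining reaches the
#' from-scratch local model's mean AUROC with a strictly smaller fraction
#' of pretraining patients.
#'
#' @param plan an [experimentPlan()].
#' @param seed overrides the plan seed.
#' @return list with logical `a`, `b`, `c`, plus `detail` tables.
#' @export
runBenchmark <- function(plan = experimentPlan(), seed = plan$seed) {
  plan$seed <- as.integer(seed)
  study <- prepareStudy(plan, seed)
  overall <- runOverallExperiment(plan, study, compare = FALSE)
  m <- overall$metrics
  mean_auroc <- function(site, model) {
    mean(m$auroc[m$site == site & m$model == model])
  }
  # averaged over both transfer directions (A-model adapted to B, B-model
  # adapted to A), as the cross-site ablation evaluates both
  ind_a <- mean(c(mean_auroc("B", "fm_external_cp"),
                  mean_auroc("A", "fm_external_cp"))) >=
    mean(c(mean_auroc("B", "fm_external"), mean_auroc("A", "fm_external")))

  # few-shot with task-train patients excluded from the adaptation corpus
  exB <- study$B$examples
  excl <- unique(exB$patient_id[exB$fold == "train"])
  ck_fs <- .continue_site(overall$checkpoints$A, study, "B", plan,
                          .stage_seed(seed, 700), exclude = excl)
  fs <- runFewShotBenchmark(plan, study, ck_fs, site = "B")
  fs_mean <- stats::aggregate(auroc ~ model, fs$summary, mean)
  ind_b <- fs_mean$auroc[fs_mean$model == "fm_plus"] >
    fs_mean$auroc[fs_mean$model == "gbm"]

  sub <- runSubsampleExperiment(plan, study, overall$checkpoints$A,
                                site = "B", continuedFull =
                                  overall$checkpoints$ApB)
  sub_mean <- attr(sub, "mean")
  local_full <- mean_auroc("B", "fm_local")
  reach <- sub_mean$fraction[sub_mean$arm == "continued" &
                               sub_mean$auroc >= local_full]
  ind_c <- length(reach) > 0 && min(reach) < 1

  auditLeakage(overall, fewshotCheckpoint = ck_fs, fewshotSite = "B")

  list(a = ind_a, b = ind_b, c = ind_c,
       detail = list(metrics = m, fewshot = fs$summary,
                     subsample = sub_mean, local_full_auroc = local_full,
                     checkpoints = overall$checkpoints))
}

#' Render a deterministic run report
#'
#' Writes a markdown summary (metric tables, comparisons, few-shot and
#' subsample results when present) from the CSV tables in a results
#' directory. Rendering is deterministic: regenerating from the same
#' inputs yields identical bytes.
#'
#' @param resultsDir directory holding `metrics.csv` and optionally
#'   `comparisons.csv`, `fewshot.csv`, `subsample.csv`.
#' @param out output file (default `summary.md` inside `resultsDir`).
#' @return the output path, invisibly.
#' @export
reportResults <- function(resultsDir, out = file.path(resultsDir, "summary.md")) {
  lines <- c("# Benchmark report", "")
  fmt_tbl <- function(d) {
    if (is.null(d) || !nrow(d)) return("(no rows)")
    num <- vapply(d, is.numeric, logical(1))
    d[num] <- lapply(d[num], function(x) sprintf("%.4f", x))
    hdr <- paste(names(d), collapse = " | ")
    sep <- paste(rep("---", ncol(d)), collapse = " | ")
    body <- apply(d, 1, paste, collapse = " | ")
    c(hdr, sep, body)
  }
  for (f in c("metrics", "comparisons", "fewshot", "subsample")) {
    path <- file.path(resultsDir, paste0(f, ".csv"))
    if (!file.exists(path)) next
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    lines <- c(lines, paste("##", f), "", fmt_tbl(d), "")
  }
  writeLines(lines, out)
  invisible(out)
}
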