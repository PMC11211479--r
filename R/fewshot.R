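# Label-efficiency experiment: balanced k-shot sampling with the k_p rule,
# repeated sampling iterations, and exclusion of task-train patients from
# the pretraining corpus so pretraining never sees task examples.

#' Few-shot experiment design
#'
#' @param kGrid training-set sizes; ascending powers of two (default
#'   2, 4, ..., 1024).
#' @param iterations independent sampling iterations per cell (default 20).
#' @param seed global seed; per-cell seeds are derived deterministically.
#' @return list of class `fewshot_design`.
#' @export
fewShotDesign <- function(kGrid = 2L^(1:10), iterations = 20L, seed = 1L) {
  kGrid <- as.integer(kGrid)
  stopifnot(length(kGrid) >= 1, all(diff(kGrid) > 0),
            all(bitwAnd(kGrid, kGrid - 1L) == 0L), iterations >= 1)
  structure(list(kGrid = kGrid, iterations = as.integer(iterations),
                 seed = as.integer(seed)),
            class = "fewshot_design")
}

#' Deterministic per-cell seed derivation
#'
#' Hashes (global seed, task, k, iteration) into a 31-bit seed so few-shot
#' draws are reproducible yet independent across cells.
#'
#' @param globalSeed integer.
#' @param task task name.
#' @param k training-set size.
#' @param iteration iteration index.
#' @return integer seed in \[1, 2^31 - 1\].
#' @export
fewshotSeed <- function(globalSeed, task, k, iteration) {
  th <- sum(utf8ToInt(task) * seq_len(nchar(task)))
  v <- (as.numeric(globalSeed) * 1000003 + th * 8191 +
          as.numeric(k) * 131 + as.numeric(iteration)) %% (2^31 - 1)
  as.integer(v) + 1L
}

#' Balanced k-shot sampling
#'
#' Draws a training subset of total size k from the task training pool:
#' k/2 positives and k/2 negatives without replacement when enough
#' positives exist; when the pool holds only k_p < k/2 positives, all k_p
#' positives plus (k - k_p) negatives, keeping the total at k (an
#' alternative reading filling negatives only to k/2 is available via
#' `fill = "to_half"`). If k exceeds the pool, the whole pool is drawn and
#' flagged. The validation fold is never subsampled.
#'
#' @param pool data.frame of task training examples with a `label` column.
#' @param k total draw size.
#' @param seed RNG seed for this draw.
#' @param fill `"to_k"` (default) or `"to_half"`, governing how negatives
#'   complete the draw when positives are scarce.
#' @return list with `idx` (row indices into `pool`), `n_pos`, `n_neg`,
#'   `flagged` (TRUE when the whole pool was drawn).
#' @export
sampleFewShot <- function(pool, k, seed = 1L, fill = c("to_k", "to_half")) {
  fill <- match.arg(fill)
  pos <- which(pool$label == 1)
  neg <- which(pool$label == 0)
  if (!length(pos) || !length(neg)) {
    stop("few-shot pool needs at least one positive and one negative")
  }
  if (k >= nrow(pool)) {
    return(list(idx = seq_len(nrow(pool)), n_pos = length(pos),
                n_neg = length(neg), flagged = TRUE))
  }
  half <- k %/% 2L
  .run_seeded(seed, {
    if (length(pos) >= half) {
      np <- half
      nn <- k - half
    } else {
      np <- length(pos)
      nn <- if (fill == "to_k") k - np else half
    }
    nn <- min(nn, length(neg))
    ip <- if (np < length(pos)) sample(pos, np) else pos
    in_ <- if (nn < length(neg)) sample(neg, nn) else neg
    list(idx = c(ip, in_), n_pos = np, n_neg = nn, flagged = FALSE)
  })
}

#' Exclude task-train patients from a pretraining corpus
#'
#' Removes every patient contributing a task-specific training example
#' from the corpus used for (continued) pretraining, so few-shot results
#' are not advantaged by pretraining exposure to task training patients.
#'
#' @param corpus a tokenized corpus from [tokenize()] (named by patient)
#'   or a [TimelineSet-class].
#' @param taskTrainPatients character vector of patient ids to remove.
#' @return the reduced corpus, same type as the input.
#' @export
excludeTaskPatientsFromPretraining <- function(corpus, taskTrainPatients) {
  if (is(corpus, "TimelineSet")) {
    keep <- setdiff(persons(corpus)$patient_id, taskTrainPatients)
    return(subsetPatients(corpus, keep))
  }
  keep <- setdiff(names(corpus), taskTrainPatients)
  out <- corpus[keep]
  attr(out, "vocab_codes") <- attr(corpus, "vocab_codes")
  out
}

#' Run the few-shot experiment grid
#'
#' For every (model arm, task, k, iteration) cell: draw a balanced k-shot
#' training sample from the task training fold, retrain the arm's head
#' from scratch with the standard tuning procedure (the full validation
#' fold is never subsampled), evaluate on the task test fold, and record
#' AUROC and prior-corrected ECE. Cell seeds derive deterministically from
#' (seed, task, k, iteration). Cells whose head degenerates to a
#' single-class constant are marked missing.
#'
#' @param arms named list of model arms; each arm is a list with `kind`
#'   (`"fm"` for linear probes, `"count"` for the GBM baseline) and
#'   `feat`, a list mapping task name to a list of `train`, `valid`,
#'   `test` feature matrices row-aligned with the task folds.
#' @param tasks named list mapping task name to a list of `train`,
#'   `valid`, `test` data.frames each containing a `label` column.
#' @param design a [fewShotDesign()].
#' @param bins ECE quantile bins.
#' @param fill negative-completion rule, see [sampleFewShot()].
#' @return data.frame with one row per cell: `model`, `task`, `k`,
#'   `iteration`, `auroc`, `ece_corrected`.
#' @export
runFewShotExperiment <- function(arms, tasks, design = fewShotDesign(),
                                 bins = 10L, fill = "to_k") {
  rows <- list()
  for (tn in names(tasks)) {
    folds <- tasks[[tn]]
    pool <- folds$train
    if (sum(pool$label == 1) < 1 || sum(pool$label == 0) < 1) next
    b_prime <- mean(pool$label)   # task outcome rate for prior correction
    y_va <- folds$valid$label
    y_te <- folds$test$label
    for (k in design$kGrid) {
      for (it in seq_len(design$iterations)) {
        cell_seed <- fewshotSeed(design$seed, tn, k, it)
        draw <- sampleFewShot(pool, k, seed = cell_seed, fill = fill)
        y_tr <- pool$label[draw$idx]
        for (an in names(arms)) {
          arm <- arms[[an]]
          f <- arm$feat[[tn]]
          x_tr <- f$train[draw$idx, , drop = FALSE]
          head <- if (arm$kind == "count") {
            fitGbmHead(x_tr, y_tr, f$valid, y_va, seed = cell_seed)
          } else {
            fitLinearHead(x_tr, y_tr, f$valid, y_va, seed = cell_seed)
          }
          if (isTRUE(head@flags$constant_fallback)) {
            au <- NA_real_; ec <- NA_real_
          } else {
            p_te <- predictHead(head, f$test)
            au <- auroc(p_te, y_te)
            pc <- priorCorrect(p_te, b_prime)
            ec <- if (length(pc) >= bins) eceQuantile(pc, y_te, bins)
                  else NA_real_
          }
          rows[[length(rows) + 1L]] <- data.frame(
            model = an, task = tn, k = k, iteration = it,
            auroc = au, ece_corrected = ec)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Average few-shot results over iterations
#'
#' @param results data.frame from [runFewShotExperiment()].
#' @return data.frame with mean `auroc`/`ece_corrected` per
#'   (model, task, k), NA cells dropped from the mean.
#' @export
summarizeFewShot <- function(results) {
  dt <- data.table::as.data.table(results)
  out <- dt[, list(auroc = mean(auroc, na.rm = TRUE),
                   ece_corrected = mean(ece_corrected, na.rm = TRUE),
                   n_iter = sum(is.finite(auroc))),
            by = c("model", "task", "k")]
  as.data.frame(out)
}
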