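#' Area under the ROC curve
#'
#' Computes the probability that a randomly chosen positive example receives
#' a higher predicted score than a randomly chosen negative example, with
#' tied scores counted one half. Equivalent to exhaustive positive-negative
#' pair counting (midrank formulation of the Mann-Whitney statistic).
#'
#' @param score numeric vector of predicted scores or risks.
#' @param label binary vector (0/1, or logical) of outcomes.
#' @return AUROC in \[0, 1\].
#' @examples
#' auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
auroc <- function(score, label) {
  label <- as.integer(label)
  stopifnot(length(score) == length(label), all(label %in% c(0L, 1L)))
  if (!all(is.finite(score))) stop("scores must be finite")
  n1 <- sum(label)
  if (n1 == 0L || n1 == length(label)) {
    stop("AUROC undefined: only one class present")
  }
  .cpp_auroc(as.numeric(score), label)
}

#' Prior correction of balanced-training predicted risks
#'
#' Maps probabilities learned under an (approximately) balanced class prior
#' back to the deployment outcome rate `bPrime`:
#' \deqn{p' = \frac{p}{p + (1-p)(1-b')/b'}}
#' The map is strictly increasing in `p`, fixes 0 and 1, and is the identity
#' when `bPrime = 0.5`. Used before computing calibration error for models
#' trained on balanced few-shot samples.
#'
#' @param p numeric vector of predicted risks in \[0, 1\].
#' @param bPrime scalar task outcome rate in (0, 1).
#' @return corrected risks, same length as `p`.
#' @examples
#' priorCorrect(0.5, 0.1)           # 0.1
#' priorCorrect(0.8, 0.25)          # 0.2 / 0.35
#' @export
priorCorrect <- function(p, bPrime) {
  if (length(bPrime) != 1L || !is.finite(bPrime) || bPrime <= 0 || bPrime >= 1) {
    stop("bPrime must be a single value in (0, 1)")
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0, 1]")
  p / (p + (1 - p) * (1 - bPrime) / bPrime)
}

#' Expected calibration error with quantile bins
#'
#' Partitions examples into `bins` groups by quantiles of the predicted risk
#' (type-7 quantile edges; duplicated edges from tied risks are merged) and
#' returns the bin-size-weighted mean absolute gap between mean predicted
#' risk and observed outcome rate. When all risks fall in a single bin the
#' degenerate value `|mean(p) - prevalence|` is returned.
#'
#' @param p numeric vector of predicted risks in \[0, 1\].
#' @param label binary outcome vector.
#' @param bins number of quantile bins (default 10).
#' @return ECE in \[0, 1\].
#' @examples
#' eceQuantile(c(0.2, 0.2, 0.8, 0.8), c(0, 1, 1, 1), bins = 2)  # 0.25
#' @export
eceQuantile <- function(p, label, bins = 10L) {
  label <- as.integer(label)
  stopifnot(length(p) == length(label), all(label %in% c(0L, 1L)))
  if (length(p) < bins) {
    stop("need at least `bins` examples")
  }
  if (!all(is.finite(p))) stop("risks must be finite")
  .cpp_ece(as.numeric(p), label, as.integer(bins))
}

#' Hierarchical bootstrap comparison of two models
#'
#' Compares two models evaluated on identical example sets across one or
#' more prediction tasks. Each bootstrap replicate resamples tasks with
#' replacement (the outer level; disable with `nested = FALSE` for flat
#' patient-only resampling), then examples (patients) with replacement
#' within each resampled task, and recomputes the mean metric difference
#' A - B. The two-tailed p-value is twice the smaller tail proportion of
#' replicate differences relative to 0, with replicates exactly at 0
#' counted half in each tail, capped at 1.
#'
#' @param predsA,predsB data.frames with columns `task`, `p` (predicted
#'   risk) and `label`, row-aligned across the two models within each task.
#' @param metric `"auroc"` or `"ece"`.
#' @param B number of bootstrap replicates (default 1000).
#' @param seed integer RNG seed for the resampling.
#' @param nested resample tasks as the outer level (default TRUE).
#' @param bins quantile bins when `metric = "ece"`.
#' @return a [ComparisonResult-class] object.
#' @export
hierarchicalBootstrapDiff <- function(predsA, predsB, metric = c("auroc", "ece"),
                                      B = 1000L, seed = 1L, nested = TRUE,
                                      bins = 10L) {
  metric <- match.arg(metric)
  stopifnot(is.data.frame(predsA), is.data.frame(predsB))
  need <- c("task", "p", "label")
  if (!all(need %in% names(predsA)) || !all(need %in% names(predsB))) {
    stop("predsA/predsB need columns task, p, label")
  }
  if (B < 100L) warning("fewer than 100 bootstrap replicates: CI and p unstable")
  tasksA <- split(predsA, predsA$task)
  tasksB <- split(predsB, predsB$task)
  if (!identical(sort(names(tasksA)), sort(names(tasksB)))) {
    stop("the two models must be evaluated on the same tasks")
  }
  task_names <- sort(names(tasksA))
  if (length(task_names) == 1L && nested) {
    # outer resampling over a single task is the identity
    nested <- FALSE
  }
  point_fun <- function(p, y) {
    if (metric == "auroc") auroc(p, y) else eceQuantile(p, y, bins)
  }
  per_task <- vapply(task_names, function(tn) {
    a <- tasksA[[tn]]; b <- tasksB[[tn]]
    stopifnot(nrow(a) == nrow(b), all(a$label == b$label))
    point_fun(a$p, a$label) - point_fun(b$p, b$label)
  }, numeric(1))
  payload <- lapply(task_names, function(tn) {
    list(a = as.numeric(tasksA[[tn]]$p), b = as.numeric(tasksB[[tn]]$p),
         y = as.integer(tasksA[[tn]]$label))
  })
  reps <- .cpp_hier_bootstrap(payload, as.integer(B), as.integer(seed),
                              isTRUE(nested), metric, as.integer(bins))
  reps <- reps[is.finite(reps)]
  ci <- unname(stats::quantile(reps, c(0.025, 0.975), type = 7))
  n_lo <- sum(reps < 0) + 0.5 * sum(reps == 0)
  n_hi <- sum(reps > 0) + 0.5 * sum(reps == 0)
  p_one <- min(n_lo, n_hi) / length(reps)
  p_two <- min(1, 2 * p_one)
  new("ComparisonResult",
      metric = metric,
      perTaskDiff = per_task,
      meanDiff = mean(per_task),
      ci = ci,
      pValue = p_two,
      replicates = length(reps),
      seed = as.integer(seed))
}
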