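#' TimelineSet: patient timelines in an OMOP-lite tabular dialect
#'
#' Columnar container for a population of patient medical timelines:
#' demographics (`persons`), time-ordered coded events with optional numeric
#' lab values (`events`), and hospital admissions (`admissions`). All
#' timestamps are stored as integer minutes from the Unix epoch so that
#' calendar-day boundaries ("midnight") are exact. Events are kept sorted by
#' patient, then time, then original input order (stable within ties).
#'
#' @slot persons data.frame with columns `patient_id`, `birth_date`, `sex`,
#'   `site`.
#' @slot events data.frame with columns `patient_id`, `time`, `code`,
#'   `value` (NA unless the code is a numeric lab).
#' @slot admissions data.frame with columns `patient_id`, `admit_time`,
#'   `discharge_time`, `death_time` (NA when absent).
#' @aliases TimelineSet-class
#' @exportClass TimelineSet
setClass("TimelineSet",
  representation(persons = "data.frame", events = "data.frame",
                 admissions = "data.frame"))

setValidity("TimelineSet", function(object) {
  msgs <- character()
  pc <- c("patient_id", "birth_date", "sex", "site")
  ec <- c("patient_id", "time", "code", "value")
  ac <- c("patient_id", "admit_time", "discharge_time", "death_time")
  if (!all(pc %in% names(object@persons))) {
    msgs <- c(msgs, paste("persons missing column:",
                          paste(setdiff(pc, names(object@persons)), collapse = ", ")))
  }
  if (!all(ec %in% names(object@events))) {
    msgs <- c(msgs, paste("events missing column:",
                          paste(setdiff(ec, names(object@events)), collapse = ", ")))
  }
  if (!all(ac %in% names(object@admissions))) {
    msgs <- c(msgs, paste("admissions missing column:",
                          paste(setdiff(ac, names(object@admissions)), collapse = ", ")))
  }
  if (length(msgs)) return(msgs)
  if (nrow(object@events)) {
    if (anyNA(object@events$time) || !all(is.finite(object@events$time))) {
      msgs <- c(msgs, "event times must be finite")
    }
    if (!all(object@events$patient_id %in% object@persons$patient_id)) {
      msgs <- c(msgs, "events reference unknown patient_id")
    }
    # patient blocks may appear in any order; times must be sorted within
    # each patient (stable in input order within ties)
    tt <- split(object@events$time, object@events$patient_id)
    if (any(vapply(tt, is.unsorted, logical(1)))) {
      msgs <- c(msgs, "events must be sorted non-decreasing in time within patient")
    }
  }
  if (nrow(object@admissions)) {
    d <- object@admissions
    bad <- !is.na(d$discharge_time) & d$discharge_time < d$admit_time
    if (any(bad)) msgs <- c(msgs, "discharge_time before admit_time")
  }
  if (length(msgs)) msgs else TRUE
})

#' Vocabulary: frequency-ranked code-to-token map
#'
#' Codes are ranked by total corpus occurrence count (descending), ties
#' broken lexicographically by code string, truncated to at most `maxSize`
#' entries. Codes outside the vocabulary have no token and are dropped at
#' tokenization time (out-of-vocabulary semantics).
#'
#' @slot codes character vector in rank order (rank 1 first).
#' @slot counts numeric occurrence counts aligned with `codes`.
#' @slot maxSize integer capacity K.
#' @aliases Vocabulary-class
#' @exportClass Vocabulary
setClass("Vocabulary",
  representation(codes = "character", counts = "numeric", maxSize = "integer"))

setValidity("Vocabulary", function(object) {
  if (length(object@codes) != length(object@counts)) {
    return("codes and counts lengths differ")
  }
  if (length(object@codes) > object@maxSize) return("more codes than maxSize")
  if (anyDuplicated(object@codes)) return("duplicate codes")
  if (length(object@counts) > 1) {
    d <- diff(object@counts)
    if (any(d > 0)) return("counts must be non-increasing in rank")
    ties <- which(d == 0)
    for (i in ties) {
      if (object@codes[i] > object@codes[i + 1]) {
        return("tied counts must be ordered lexicographically by code")
      }
    }
  }
  TRUE
})

#' FMCheckpoint: trained foundation-model state
#'
#' Parameter state of the miniature next-code transformer together with the
#' vocabulary it was trained against, the training configuration, and
#' provenance (from-scratch site, or the parent checkpoint it was adapted
#' from by continued pretraining, plus step counts and final validation
#' loss). The vocabulary of a continued checkpoint is always inherited from
#' its parent, never rebuilt.
#'
#' @slot params named list of parameter matrices.
#' @slot vocabulary a [Vocabulary-class].
#' @slot config named list, see [fmConfig()].
#' @slot provenance named list: `kind` ("from_scratch" or "continued"),
#'   `site`, `parent_site`, `steps`, `best_step`, `valid_loss`,
#'   `learning_rate`.
#' @aliases FMCheckpoint-class
#' @exportClass FMCheckpoint
setClass("FMCheckpoint",
  representation(params = "list", vocabulary = "Vocabulary",
                 config = "list", provenance = "list"))

#' FittedHead: a supervised task head
#'
#' Either a gradient-boosted tree classifier over count features or an
#' L2-regularized logistic probe over frozen foundation-model
#' representations, with the hyperparameters chosen on the task validation
#' fold by log loss.
#'
#' @slot kind "gbm" or "linear".
#' @slot featureKind "count" or "fm".
#' @slot state fitted model object (implementation-specific).
#' @slot hyper named list of chosen hyperparameters.
#' @slot validLogLoss validation log loss of the chosen configuration.
#' @slot featureNames column names the head expects, in order.
#' @slot flags list of fit diagnostics (e.g. `constant_fallback`).
#' @aliases FittedHead-class
#' @exportClass FittedHead
setClass("FittedHead",
  representation(kind = "character", featureKind = "character", state = "ANY",
                 hyper = "list", validLogLoss = "numeric",
                 featureNames = "character", flags = "list"))

#' ComparisonResult: hierarchical-bootstrap model comparison
#'
#' Per-task and mean metric differences (model A minus model B) with a 95%
#' hierarchical bootstrap confidence interval and a two-tailed p-value.
#'
#' @slot metric "auroc" or "ece".
#' @slot perTaskDiff named numeric vector of per-task differences.
#' @slot meanDiff mean difference across tasks.
#' @slot ci length-2 numeric (2.5 and 97.5 percentiles of replicates).
#' @slot pValue two-tailed bootstrap p-value.
#' @slot replicates number of finite bootstrap replicates used.
#' @slot seed resampling seed.
#' @aliases ComparisonResult-class
#' @exportClass ComparisonResult
setClass("ComparisonResult",
  representation(metric = "character", perTaskDiff = "numeric",
                 meanDiff = "numeric", ci = "numeric", pValue = "numeric",
                 replicates = "integer", seed = "integer"))

setValidity("ComparisonResult", function(object) {
  if (length(object@ci) != 2) return("ci must have length 2")
  if (object@pValue < 0 || object@pValue > 1) return("pValue outside [0, 1]")
  TRUE
})

setMethod("show", "TimelineSet", function(object) {
  cat("TimelineSet with", nrow(object@persons), "patients,",
      nrow(object@events), "events,", nrow(object@admissions), "admissions\n")
  if (nrow(object@persons)) {
    st <- table(object@persons$site)
    cat("  sites:", paste(sprintf("%s (n=%d)", names(st), as.integer(st)),
                          collapse = ", "), "\n")
  }
})

setMethod("show", "Vocabulary", function(object) {
  cat("Vocabulary of", length(object@codes), "codes (maxSize",
      object@maxSize, ")\n")
  if (length(object@codes)) {
    k <- min(5L, length(object@codes))
    cat("  top codes:", paste(sprintf("%s(%g)", object@codes[seq_len(k)],
                                      object@counts[seq_len(k)]),
                              collapse = " "), "\n")
  }
})

setMethod("show", "FMCheckpoint", function(object) {
  pv <- object@provenance
  cat(sprintf("FMCheckpoint [%s, site %s]%s\n",
              pv$kind %||% "?", pv$site %||% "?",
              if (!is.null(pv$parent_site)) paste0(" continued from ", pv$parent_site) else ""))
  cat(sprintf("  d=%d layers=%d window=%d vocab=%d | steps=%s valid loss=%s\n",
              object@config$hidden_size, object@config$n_layers,
              object@config$attn_window, length(object@vocabulary@codes),
              pv$steps %||% "?", signif(pv$valid_loss %||% NA_real_, 4)))
})

setMethod("show", "FittedHead", function(object) {
  cat(sprintf("FittedHead [%s on %s features] valid log loss %.4f\n",
              object@kind, object@featureKind, object@validLogLoss))
})

setMethod("show", "ComparisonResult", function(object) {
  cat(sprintf("ComparisonResult (%s): mean diff %+0.4f [%.4f, %.4f], two-tailed p = %.4g (%d replicates)\n",
              object@metric, object@meanDiff, object@ci[1], object@ci[2],
              object@pValue, object@replicates))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
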