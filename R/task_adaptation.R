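# Supervised task heads: count-featurized gradient-boosted trees (the
# conventional baseline) and L2-regularized logistic probes on frozen
# foundation-model representations. All hyperparameters are chosen on the
# task validation fold by log loss; the test fold never influences tuning.

.logloss <- function(p, y) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Count featurization of patient histories
#'
#' The conventional baseline representation: for each example, per-code
#' occurrence counts over the full observation window (all events strictly
#' before the prediction time), plus age at prediction in days and a sex
#' indicator. The code feature space is the set of codes seen in the task
#' training fold (pass `featureCodes`); codes outside it are ignored.
#'
#' @param examples data.frame with `patient_id`, `prediction_time`.
#' @param timelines a [TimelineSet-class].
#' @param featureCodes character vector defining the code feature space;
#'   default: all codes present in `timelines`.
#' @return sparse `dgCMatrix` (rows = examples) with named columns:
#'   the codes, then `age_days`, `sex_male`.
#' @export
countFeaturize <- function(examples, timelines, featureCodes = NULL) {
  stopifnot(all(c("patient_id", "prediction_time") %in% names(examples)))
  ev <- events(timelines)
  per <- persons(timelines)
  if (is.null(featureCodes)) featureCodes <- sort(unique(ev$code))
  code_idx <- match(ev$code, featureCodes)
  by_pat <- split(seq_len(nrow(ev)), ev$patient_id)
  n <- nrow(examples)
  trip_i <- list(); trip_j <- list(); trip_x <- list()
  for (i in seq_len(n)) {
    ix <- by_pat[[examples$patient_id[i]]]
    if (is.null(ix)) next
    ix <- ix[ev$time[ix] < examples$prediction_time[i]]
    ci <- code_idx[ix]
    ci <- ci[!is.na(ci)]
    if (!length(ci)) next
    tab <- tabulate(ci, nbins = length(featureCodes))
    nz <- which(tab > 0)
    trip_i[[i]] <- rep(i, length(nz)); trip_j[[i]] <- nz; trip_x[[i]] <- tab[nz]
  }
  m <- Matrix::sparseMatrix(
    i = unlist(trip_i), j = unlist(trip_j), x = unlist(trip_x),
    dims = c(n, length(featureCodes)),
    dimnames = list(NULL, featureCodes))
  pi <- match(examples$patient_id, per$patient_id)
  age <- (examples$prediction_time - per$birth_date[pi]) / MINUTES_PER_DAY
  sexm <- as.numeric(per$sex[pi] == "M")
  out <- cbind(m, Matrix::Matrix(cbind(age_days = age, sex_male = sexm),
                                 sparse = TRUE))
  colnames(out) <- c(featureCodes, "age_days", "sex_male")
  methods::as(out, "CsparseMatrix")
}

.constant_head <- function(rate, kind, featureKind, featureNames) {
  rate <- min(max(rate, 1e-6), 1 - 1e-6)
  new("FittedHead", kind = kind, featureKind = featureKind,
      state = list(constant = rate), hyper = list(),
      validLogLoss = NA_real_, featureNames = featureNames,
      flags = list(constant_fallback = TRUE))
}

#' Fit the gradient-boosted tree baseline head
#'
#' Grid search over learning rate, leaf count and boosting-algorithm
#' variant (standard gradient boosting vs dart), each with early-stopped
#' rounds on the validation fold; the configuration with the best
#' validation log loss wins. If the training fold contains a single class,
#' a constant-rate fallback head is returned and flagged.
#'
#' @param xTrain,xValid feature matrices (sparse ok) with identical columns.
#' @param yTrain,yValid binary labels.
#' @param grid data.frame of candidate settings with columns `eta`,
#'   `max_leaves`, `booster`; default the package grid.
#' @param seed RNG seed passed to the booster.
#' @param nrounds,earlyStoppingRounds boosting-round budget and patience.
#' @return a [FittedHead-class] of kind `"gbm"`.
#' @export
fitGbmHead <- function(xTrain, yTrain, xValid, yValid, grid = NULL,
                       seed = 1L, nrounds = 500L, earlyStoppingRounds = 25L) {
  if (nrow(xTrain) == 0) stop("empty training set")
  fn <- colnames(xTrain)
  if (is.null(fn)) fn <- paste0("f", seq_len(ncol(xTrain)))
  if (length(unique(yTrain)) < 2) {
    return(.constant_head(mean(yTrain), "gbm", "count", fn))
  }
  if (is.null(grid)) {
    grid <- expand.grid(eta = c(0.1, 0.03), max_leaves = c(15L, 31L),
                        booster = c("gbtree", "dart"),
                        stringsAsFactors = FALSE)
  }
  dtr <- xgboost::xgb.DMatrix(methods::as(xTrain, "CsparseMatrix"),
                              label = yTrain)
  dva <- xgboost::xgb.DMatrix(methods::as(xValid, "CsparseMatrix"),
                              label = yValid)
  best <- NULL
  for (gi in seq_len(nrow(grid))) {
    params <- list(objective = "binary:logistic",
                   eval_metric = "logloss",
                   booster = grid$booster[gi],
                   eta = grid$eta[gi],
                   tree_method = "hist",
                   grow_policy = "lossguide",
                   max_depth = 0L,
                   max_leaves = grid$max_leaves[gi],
                   nthread = 1L,
                   seed = as.integer(seed))
    fit <- xgboost::xgb.train(params, dtr, nrounds = nrounds,
                              evals = list(valid = dva),
                              early_stopping_rounds = earlyStoppingRounds,
                              verbose = 0)
    att <- attributes(fit)
    score <- att$best_score
    if (is.null(score)) {
      pv <- predict(fit, dva)
      score <- .logloss(pv, yValid)
    }
    if (is.null(best) || score < best$score) {
      best <- list(fit = fit, score = score,
                   hyper = c(as.list(grid[gi, ]),
                             list(best_iteration = att$best_iteration)))
    }
  }
  new("FittedHead", kind = "gbm", featureKind = "count", state = best$fit,
      hyper = best$hyper, validLogLoss = as.numeric(best$score),
      featureNames = fn, flags = list(constant_fallback = FALSE))
}

.ridge_logistic <- function(x, y, lambda, w0 = NULL) {
  x <- as.matrix(x)
  d <- ncol(x)
  if (is.null(w0)) w0 <- numeric(d + 1)
  nll <- function(w) {
    eta <- drop(x %*% w[-1]) + w[1]
    # log(1+exp(-|eta|)) formulation for stability
    -sum(y * eta - pmax(eta, 0) - log1p(exp(-abs(eta)))) +
      0.5 * lambda * sum(w[-1]^2)
  }
  grd <- function(w) {
    eta <- drop(x %*% w[-1]) + w[1]
    r <- plogis(eta) - y
    c(sum(r), drop(crossprod(x, r)) + lambda * w[-1])
  }
  fit <- stats::optim(w0, nll, grd, method = "L-BFGS-B",
                      control = list(maxit = 500, factr = 1e4))
  fit$par
}

#' Fit an L2-regularized logistic probe
#'
#' The linear task head over frozen representations: logistic regression
#' with an L2 penalty on the weights (intercept unpenalized), minimized
#' with L-BFGS. The inverse-regularization strength C is selected from
#' `cGrid` by validation log loss (penalty = 1/(2C) ||w||^2). Returns
#' probabilities strictly inside (0, 1).
#'
#' @param xTrain,xValid dense representation matrices.
#' @param yTrain,yValid binary labels.
#' @param cGrid inverse-regularization candidates.
#' @param seed accepted for interface symmetry; the fit is deterministic.
#' @return a [FittedHead-class] of kind `"linear"`.
#' @export
fitLinearHead <- function(xTrain, yTrain, xValid, yValid,
                          cGrid = c(1e-2, 1e-1, 1, 10), seed = 1L) {
  xTrain <- as.matrix(xTrain); xValid <- as.matrix(xValid)
  if (!all(is.finite(xTrain)) || !all(is.finite(xValid))) {
    stop("non-finite features")
  }
  fn <- colnames(xTrain)
  if (is.null(fn)) fn <- paste0("f", seq_len(ncol(xTrain)))
  if (nrow(xTrain) == 0) stop("empty training set")
  if (length(unique(yTrain)) < 2) {
    return(.constant_head(mean(yTrain), "linear", "fm", fn))
  }
  best <- NULL
  for (C in cGrid) {
    w <- .ridge_logistic(xTrain, yTrain, lambda = 1 / C)
    pv <- plogis(drop(xValid %*% w[-1]) + w[1])
    score <- .logloss(pv, yValid)
    if (is.null(best) || score < best$score) {
      best <- list(w = w, score = score, C = C)
    }
  }
  new("FittedHead", kind = "linear", featureKind = "fm",
      state = list(coef = best$w), hyper = list(C = best$C),
      validLogLoss = best$score, featureNames = fn,
      flags = list(constant_fallback = FALSE))
}

#' Predict probabilities from a fitted head
#'
#' @param head a [FittedHead-class].
#' @param x feature matrix matching the head's feature space.
#' @return numeric vector of probabilities in \[0, 1\], one per row.
#' @export
predictHead <- function(head, x) {
  stopifnot(is(head, "FittedHead"))
  if (ncol(x) != length(head@featureNames)) {
    stop("feature dimension mismatch: head expects ",
         length(head@featureNames), " columns, got ", ncol(x))
  }
  if (isTRUE(head@flags$constant_fallback)) {
    return(rep(head@state$constant, nrow(x)))
  }
  if (head@kind == "linear") {
    w <- head@state$coef
    plogis(drop(as.matrix(x) %*% w[-1]) + w[1])
  } else {
    predict(head@state,
            xgboost::xgb.DMatrix(methods::as(x, "CsparseMatrix")))
  }
}

#' Persist / restore feature matrices
#'
#' Sparse features are written MatrixMarket-style next to a plain-text id
#' list, matching common interchange conventions.
#'
#' @param x sparse feature matrix with column names.
#' @param ids character vector of example ids (row order).
#' @param dir output directory.
#' @return `writeFeatureMatrix`: `dir` invisibly; `readFeatureMatrix`:
#'   list with `x`, `ids`.
#' @export
writeFeatureMatrix <- function(x, ids, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(x, "CsparseMatrix"),
                  file.path(dir, "features.mtx"))
  writeLines(colnames(x), file.path(dir, "columns.txt"))
  writeLines(as.character(ids), file.path(dir, "ids.txt"))
  invisible(dir)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(dir) {
  x <- methods::as(Matrix::readMM(file.path(dir, "features.mtx")),
                   "CsparseMatrix")
  colnames(x) <- readLines(file.path(dir, "columns.txt"))
  list(x = x, ids = readLines(file.path(dir, "ids.txt")))
}
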