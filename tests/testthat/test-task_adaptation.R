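test_that("count featurization counts pre-prediction events only", {
  tl <- tiny_timelines()
  # p1 events: DX/001 (day1 09:00), LAB/GLU (day2), DX/002 (day3)
  ex <- data.frame(patient_id = c("p1", "p1", "p2"),
                   prediction_time = c(dh(3), dh(1), dh(10)))
  x <- countFeaturize(ex, tl)
  expect_equal(unname(x[1, "DX/001"]), 1)
  expect_equal(unname(x[1, "LAB/GLU"]), 1)
  expect_equal(unname(x[1, "DX/002"]), 0)   # at/after prediction time only
  # empty history: all-zero code counts but demographics present
  expect_equal(sum(x[2, setdiff(colnames(x), c("age_days", "sex_male"))]), 0)
  expect_gt(x[2, "age_days"], 0)
  expect_equal(unname(x[3, "sex_male"]), 1)
  # repeated codes accumulate
  ev <- rbind(events(tl),
              data.frame(patient_id = "p1", time = dh(2, 10) + 0:2,
                         code = "DX/001", value = NA_real_))
  tl2 <- timelineSet(persons(tl), ev, admissions(tl))
  x2 <- countFeaturize(ex, tl2)
  expect_equal(unname(x2[1, "DX/001"]), 4)
  # restricted feature space ignores other codes
  x3 <- countFeaturize(ex, tl, featureCodes = "DX/001")
  expect_equal(colnames(x3), c("DX/001", "age_days", "sex_male"))
})

test_that("GBM head separates separable data and tunes deterministically", {
  set.seed(1)
  x <- matrix(rnorm(80), 40, 2)
  y <- as.integer(x[, 1] > 0)
  x[, 1] <- x[, 1] + y * 3
  xs <- Matrix::Matrix(x, sparse = TRUE); colnames(xs) <- c("a", "b")
  h <- fitGbmHead(xs, y, xs, y, seed = 3)
  expect_equal(auroc(predictHead(h, xs), y), 1)
  h2 <- fitGbmHead(xs, y, xs, y, seed = 3)
  expect_identical(h@hyper, h2@hyper)
  expect_identical(predictHead(h, xs), predictHead(h2, xs))
  expect_error(fitGbmHead(xs[0, ], integer(), xs, y), "empty")
})

test_that("GBM on label-independent features stays near chance", {
  set.seed(21)
  n <- 500
  x <- Matrix::Matrix(matrix(rnorm(n * 8), n, 8), sparse = TRUE)
  colnames(x) <- paste0("f", 1:8)
  y <- sample(rep(0:1, each = n / 2))   # permuted labels
  tr <- 1:300; va <- 301:500
  h <- fitGbmHead(x[tr, ], y[tr], x[va, ], y[va], seed = 2)
  au <- auroc(predictHead(h, x[va, ]), y[va])
  expect_gte(au, 0.35); expect_lte(au, 0.65)
})

test_that("single-class training falls back to a flagged constant head", {
  x <- Matrix::Matrix(matrix(rnorm(20), 10, 2), sparse = TRUE)
  colnames(x) <- c("a", "b")
  h <- fitGbmHead(x, rep(1L, 10), x, rep(1L, 10))
  expect_true(h@flags$constant_fallback)
  expect_true(all(predictHead(h, x) == predictHead(h, x)[1]))
  hl <- fitLinearHead(as.matrix(x), rep(0L, 10), as.matrix(x), rep(0L, 10))
  expect_true(hl@flags$constant_fallback)
})

test_that("linear probe: identity feature, constant features, determinism", {
  y <- rep(c(0L, 1L), 20)
  x <- matrix(y, ncol = 1)
  h <- fitLinearHead(x, y, x, y, cGrid = 10)
  expect_equal(auroc(predictHead(h, x), y), 1)
  expect_gt(h@state$coef[2], 2)   # steep weight on the identity feature
  # all-constant features: intercept-only limit predicts the prevalence
  xc <- matrix(1, 40, 3)
  yc <- rep(c(0L, 0L, 0L, 1L), 10)
  hc <- fitLinearHead(xc, yc, xc, yc)
  expect_equal(unname(predictHead(hc, xc)[1]), 0.25, tolerance = 1e-6)
  expect_error(fitLinearHead(matrix(c(1, NA), 2, 1), c(0L, 1L), x, y),
               "non-finite")
})

test_that("linear probe recovers the Bayes AUROC on Gaussian blobs", {
  # two isotropic blobs shifted by delta in each of 2 dims:
  # Bayes AUROC = Phi(sqrt(2) * delta / sqrt(2)) = Phi(delta * 1) per dim
  # combined Mahalanobis distance d = delta * sqrt(2); AUROC = Phi(d/sqrt(2))
  delta <- 0.994   # Phi(0.994) ~ 0.84
  set.seed(9)
  n <- 2000
  y <- rbinom(n, 1, 0.5)
  x <- matrix(rnorm(n * 2), n, 2) + delta * y
  tr <- 1:1200; va <- 1201:1600; te <- 1601:2000
  h <- fitLinearHead(x[tr, ], y[tr], x[va, ], y[va])
  au <- auroc(predictHead(h, x[te, ]), y[te])
  expect_equal(au, stats::pnorm(delta * sqrt(2) / sqrt(2)), tolerance = 0.03)
})

test_that("probe matches ridge-penalized glmnet at matched lambda", {
  set.seed(10)
  n <- 400
  x <- matrix(rnorm(n * 3), n, 3)
  y <- rbinom(n, 1, plogis(x[, 1] - 0.5 * x[, 2]))
  h <- fitLinearHead(x[1:300, ], y[1:300], x[301:400, ], y[301:400],
                     cGrid = 1)
  g <- glmnet::glmnet(x[1:300, ], y[1:300], family = "binomial", alpha = 0,
                      lambda = 1 / 300, standardize = FALSE, thresh = 1e-12)
  pg <- as.numeric(predict(g, x[301:400, ], type = "response"))
  expect_equal(predictHead(h, x[301:400, ]), pg, tolerance = 1e-5)
})

test_that("predictions are probabilities, monotone in a single feature", {
  y <- rep(c(0L, 1L), 30)
  x <- matrix(y + rnorm(60, 0, 0.1), ncol = 1)
  h <- fitLinearHead(x, y, x, y)
  grid <- matrix(seq(-2, 3, length.out = 50), ncol = 1)
  p <- predictHead(h, grid)
  expect_length(p, 50)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(diff(p) > 0))
  expect_error(predictHead(h, matrix(0, 2, 3)), "dimension mismatch")
})

test_that("tuning ignores everything but the validation fold", {
  set.seed(30)
  x <- Matrix::Matrix(matrix(rnorm(600), 200, 3), sparse = TRUE)
  colnames(x) <- paste0("f", 1:3)
  y <- rbinom(200, 1, plogis(as.matrix(x)[, 1]))
  h1 <- fitGbmHead(x[1:100, ], y[1:100], x[101:150, ], y[101:150], seed = 4)
  h2 <- fitGbmHead(x[1:100, ], y[1:100], x[101:150, ], y[101:150], seed = 4)
  expect_identical(h1@hyper, h2@hyper)   # test fold never enters the fit
  p1 <- predictHead(h1, x[151:200, ])
  p2 <- predictHead(h2, x[151:200, , drop = FALSE][sample(50), ])
  expect_setequal(round(p1, 10), round(p2, 10))
})

test_that("feature matrices round-trip through MatrixMarket", {
  tl <- tiny_timelines()
  ex <- data.frame(patient_id = c("p1", "p2"), prediction_time = dh(5))
  x <- countFeaturize(ex, tl)
  d <- file.path(tempdir(), "featmat")
  writeFeatureMatrix(x, c("e1", "e2"), d)
  back <- readFeatureMatrix(d)
  expect_equal(as.matrix(back$x), as.matrix(x), tolerance = 1e-12)
  expect_equal(back$ids, c("e1", "e2"))
})
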