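make_pool <- function(n_pos, n_neg) {
  data.frame(id = seq_len(n_pos + n_neg),
             label = rep(c(1L, 0L), c(n_pos, n_neg)))
}

test_that("balanced draws follow the k_p rule exactly", {
  pool <- make_pool(200, 800)
  d2 <- sampleFewShot(pool, 2, seed = 1)
  expect_equal(c(d2$n_pos, d2$n_neg), c(1L, 1L))
  d8 <- sampleFewShot(pool, 8, seed = 1)
  expect_equal(c(d8$n_pos, d8$n_neg), c(4L, 4L))
  # scarce positives: all k_p positives, negatives fill to k
  pool40 <- make_pool(40, 800)
  d128 <- sampleFewShot(pool40, 128, seed = 2)
  expect_equal(c(d128$n_pos, d128$n_neg), c(40L, 88L))
  expect_length(d128$idx, 128L)
  # alternative reading: negatives fill only to k/2
  dh128 <- sampleFewShot(pool40, 128, seed = 2, fill = "to_half")
  expect_equal(c(dh128$n_pos, dh128$n_neg), c(40L, 64L))
})

test_that("draws are without replacement, seeded, and flag pool exhaustion", {
  pool <- make_pool(30, 50)
  d <- sampleFewShot(pool, 16, seed = 9)
  expect_equal(anyDuplicated(d$idx), 0L)
  expect_identical(d, sampleFewShot(pool, 16, seed = 9))
  d2 <- sampleFewShot(pool, 16, seed = 10)
  expect_false(identical(sort(d$idx), sort(d2$idx)))
  big <- sampleFewShot(pool, 128, seed = 1)
  expect_true(big$flagged)
  expect_length(big$idx, 80L)
  expect_error(sampleFewShot(make_pool(0, 10), 4, seed = 1), "positive")
})

test_that("per-cell seeds are deterministic, distinct and 31-bit", {
  s1 <- fewshotSeed(7, "mortality", 16, 3)
  expect_identical(s1, fewshotSeed(7, "mortality", 16, 3))
  expect_false(s1 == fewshotSeed(7, "mortality", 16, 4))
  expect_false(s1 == fewshotSeed(7, "anemia", 16, 3))
  grid <- expand.grid(k = 2^(1:10), it = 1:20)
  seeds <- mapply(function(k, it) fewshotSeed(1, "long_los", k, it),
                  grid$k, grid$it)
  expect_true(all(seeds >= 1 & seeds <= 2^31 - 1))
  expect_equal(anyDuplicated(seeds), 0L)
})

test_that("task-train patients are excluded from pretraining corpora", {
  corpus <- setNames(lapply(1:100, function(i) list(tokens = c(0L, 1L))),
                     sprintf("p%03d", 1:100))
  attr(corpus, "vocab_codes") <- c("a", "b")
  red <- excludeTaskPatientsFromPretraining(corpus, sprintf("p%03d", 1:30))
  expect_length(red, 70L)
  expect_identical(attr(red, "vocab_codes"), c("a", "b"))
  same <- excludeTaskPatientsFromPretraining(corpus, c("zz1", "zz2"))
  expect_length(same, 100L)
  none <- excludeTaskPatientsFromPretraining(corpus, names(corpus))
  expect_length(none, 0L)
  tl <- tiny_timelines()
  tl_red <- excludeTaskPatientsFromPretraining(tl, "p1")
  expect_equal(persons(tl_red)$patient_id, "p2")
})

test_that("few-shot design validates its grid", {
  d <- fewShotDesign()
  expect_equal(d$kGrid, 2L^(1:10))
  expect_equal(d$iterations, 20L)
  expect_error(fewShotDesign(kGrid = c(2, 3)), "is not TRUE")
  expect_error(fewShotDesign(kGrid = c(8, 4)), "is not TRUE")
})

test_that("experiment grid: single iteration mean equals the cell value and permuted labels sit at chance", {
  set.seed(14)
  n <- 600
  x <- matrix(rnorm(n * 4), n, 4)
  y_info <- rbinom(n, 1, plogis(1.5 * x[, 1]))
  y_null <- sample(y_info)
  folds <- rep(c("train", "valid", "test"), c(400, 100, 100))
  mk_task <- function(y) {
    sp <- split(seq_len(n), folds)
    lapply(sp[c("train", "valid", "test")],
           function(ix) data.frame(label = y[ix]))
  }
  feats <- {
    sp <- split(seq_len(n), folds)
    lapply(sp[c("train", "valid", "test")],
           function(ix) x[ix, , drop = FALSE])
  }
  arms <- list(probe = list(kind = "fm",
                            feat = list(info = feats, null = feats)))
  tasks <- list(info = mk_task(y_info), null = mk_task(y_null))
  res <- runFewShotExperiment(arms, tasks,
                              fewShotDesign(kGrid = c(64L), iterations = 1L,
                                            seed = 5))
  sm <- summarizeFewShot(res)
  expect_equal(nrow(res), 2L)
  expect_equal(sm$auroc, res$auroc[match(sm$task, res$task)])
  # informative task well above chance; permuted task near chance
  res3 <- runFewShotExperiment(arms, tasks,
                               fewShotDesign(kGrid = c(64L),
                                             iterations = 3L, seed = 5))
  sm3 <- summarizeFewShot(res3)
  expect_gt(sm3$auroc[sm3$task == "info"], 0.7)
  expect_gt(sm3$auroc[sm3$task == "null"], 0.35)
  expect_lt(sm3$auroc[sm3$task == "null"], 0.65)
})

test_that("mean AUROC increases with k on an informative task", {
  set.seed(15)
  n <- 900
  x <- matrix(rnorm(n * 6), n, 6)
  y <- rbinom(n, 1, plogis(0.8 * x[, 1] - 0.5 * x[, 2]))
  folds <- rep(c("train", "valid", "test"), c(600, 150, 150))
  sp <- split(seq_len(n), folds)
  feats <- lapply(sp[c("train", "valid", "test")],
                  function(ix) x[ix, , drop = FALSE])
  tasks <- list(t = lapply(sp[c("train", "valid", "test")],
                           function(ix) data.frame(label = y[ix])))
  arms <- list(probe = list(kind = "fm", feat = list(t = feats)))
  res <- runFewShotExperiment(arms, tasks,
                              fewShotDesign(kGrid = c(4L, 16L, 64L, 256L),
                                            iterations = 6L, seed = 2))
  sm <- summarizeFewShot(res)
  rho <- stats::cor(log2(sm$k), sm$auroc, method = "spearman")
  expect_gt(rho, 0)
})
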