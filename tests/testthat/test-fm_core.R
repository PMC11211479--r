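make_vocab <- function(codes) {
  new("Vocabulary", codes = codes, counts = rep(1, length(codes)),
      maxSize = length(codes))
}

as_corpus <- function(seqs, vocab = NULL) {
  out <- lapply(seqs, function(s) list(tokens = as.integer(s),
                                       times = seq_along(s),
                                       dropped = 0L))
  names(out) <- paste0("p", seq_along(out))
  if (!is.null(vocab)) attr(out, "vocab_codes") <- vocab@codes
  out
}

tiny_fm_config <- function(...) {
  base <- list(n_layers = 1L, hidden_size = 16L, n_heads = 2L,
               attn_window = 8L, max_seq_len = 32L, lr_candidates = 3e-3,
               batch_tokens = 256L, max_steps = 300L, eval_every = 25L,
               patience = 150L)
  do.call(fmConfig, utils::modifyList(base, list(...)))
}

test_that("vocabulary ranks by frequency with lexicographic tie-break", {
  codes <- c(rep("A", 5), rep("B", 3), rep("C", 3), "D")
  v <- buildVocabulary(codes, K = 3)
  expect_equal(vocabCodes(v), c("A", "B", "C"))
  expect_equal(vocabCounts(v), c(5, 3, 3))
  v_all <- buildVocabulary(codes, K = 100)
  expect_equal(vocabCodes(v_all), c("A", "B", "C", "D"))
  expect_error(buildVocabulary(codes, K = 0), "at least 1")
})

test_that("tokenization drops OOV codes, preserves order, counts drops", {
  tl <- tiny_timelines()
  v <- buildVocabulary(c("DX/001", "DX/002", "LAB/GLU"), K = 10)
  tok <- tokenize(tl, v)
  # p1 events: DX/001, LAB/GLU, DX/002 all in vocab
  expect_equal(length(tok$p1$tokens), 3L)
  expect_equal(tok$p1$dropped, 0L)
  # p2 events: DX/001 in vocab, DX/003 dropped
  expect_equal(length(tok$p2$tokens), 1L)
  expect_equal(tok$p2$dropped, 1L)
  v_none <- buildVocabulary("ZZZ", K = 5)
  tok2 <- tokenize(tl, v_none)
  expect_equal(length(tok2$p1$tokens), 0L)
  expect_equal(tok2$p1$dropped, 3L)
})

test_that("analytic gradients match finite differences", {
  cfg <- list(vocab_size = 6L, max_seq_len = 12L, hidden_size = 8L,
              n_layers = 2L, n_heads = 2L, attn_window = 4L, seed = 5L)
  p <- ehrfm:::.cpp_fm_init(cfg)
  seqs <- list(c(0L, 1L, 2L, 3L, 4L, 5L, 0L, 2L), c(3L, 1L, 4L, 1L))
  g <- ehrfm:::.cpp_fm_grad(p, seqs, cfg)
  eps <- 1e-5
  set.seed(2)
  for (nm in c("emb", "pos", "l0_wq", "l0_wo", "l0_w1", "l1_wv",
               "l1_ln2_g", "lnf_b", "wout")) {
    i <- sample(length(p[[nm]]), 1)
    p2 <- p; p2[[nm]][i] <- p2[[nm]][i] + eps
    up <- ehrfm:::.cpp_fm_loss(p2, seqs, cfg)
    p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
    dn <- ehrfm:::.cpp_fm_loss(p2, seqs, cfg)
    fd <- (up - dn) / (2 * eps)
    expect_equal(g$grads[[nm]][i], fd, tolerance = 1e-4,
                 label = paste("gradient of", nm))
  }
})

test_that("causal masking: future tokens never affect past hidden states", {
  cfg <- list(vocab_size = 6L, max_seq_len = 16L, hidden_size = 8L,
              n_layers = 2L, n_heads = 2L, attn_window = 6L, seed = 5L)
  p <- ehrfm:::.cpp_fm_init(cfg)
  s1 <- c(0L, 1L, 2L, 3L, 4L, 5L, 0L, 1L)
  s2 <- s1; s2[6:8] <- c(2L, 2L, 2L)   # perturb tokens 6..8
  h1 <- ehrfm:::.cpp_fm_hidden(p, s1, cfg)
  h2 <- ehrfm:::.cpp_fm_hidden(p, s2, cfg)
  expect_equal(h1[1:5, ], h2[1:5, ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(h1[6, ], h2[6, ])))
})

test_that("a single-code corpus is learned to near-zero cross-entropy", {
  v <- make_vocab("A")
  corp <- as_corpus(replicate(8, rep(0L, 20), simplify = FALSE), v)
  ck <- pretrainFM(corp, corp, v, tiny_fm_config(max_steps = 150L,
                                                 patience = 100L),
                   seed = 1, site = "X")
  expect_lte(provenance(ck)$valid_loss, 0.01)
})

test_that("an i.i.d. corpus converges to the unigram entropy", {
  probs <- c(0.30, 0.22, 0.16, 0.12, 0.08, 0.06, 0.04, 0.02)
  H <- -sum(probs * log(probs))
  set.seed(4)
  seqs <- replicate(60, sample(0:7, 40, replace = TRUE, prob = probs),
                    simplify = FALSE)
  v <- make_vocab(paste0("C", 1:8))
  corp <- as_corpus(seqs[1:48], v); vcorp <- as_corpus(seqs[49:60], v)
  ck <- pretrainFM(corp, vcorp, v, tiny_fm_config(), seed = 2, site = "X")
  expect_lt(abs(provenance(ck)$valid_loss - H), 0.05)
})

test_that("continued pretraining cannot end worse than its parent", {
  Tm <- matrix(c(0.8, 0.15, 0.05,
                 0.1, 0.7, 0.2,
                 0.25, 0.05, 0.7), 3, 3, byrow = TRUE)
  v <- make_vocab(paste0("S", 1:3))
  tr <- as_corpus(markovCorpus(Tm, 40, 40, seed = 5), v)
  va <- as_corpus(markovCorpus(Tm, 12, 40, seed = 6), v)
  cfg <- tiny_fm_config(max_steps = 120L, patience = 80L)
  parent <- pretrainFM(tr, va, v, cfg, seed = 3, site = "X")
  child <- continuePretrainFM(parent, tr, va, cfg, seed = 4, site = "X")
  expect_lte(provenance(child)$valid_loss,
             provenance(parent)$valid_loss + 0.01)
  expect_equal(provenance(child)$kind, "continued")
  expect_equal(provenance(child)$parent_site, "X")
  expect_identical(vocabCodes(fmVocabulary(child)), vocabCodes(v))
})

test_that("zero-step continuation returns the parent parameters unchanged", {
  v <- make_vocab(paste0("S", 1:3))
  tr <- as_corpus(list(c(0L, 1L, 2L, 0L, 1L), c(2L, 1L, 0L)), v)
  cfg <- tiny_fm_config(max_steps = 30L, patience = 10L)
  parent <- pretrainFM(tr, tr, v, cfg, seed = 1, site = "X")
  cfg0 <- cfg; cfg0$max_steps <- 0L
  child <- continuePretrainFM(parent, tr, tr, cfg0, seed = 1, site = "X")
  expect_identical(child@params, parent@params)
})

test_that("vocabulary mismatch aborts continued pretraining", {
  v1 <- make_vocab(paste0("S", 1:3))
  v2 <- make_vocab(paste0("T", 1:3))
  tr1 <- as_corpus(list(c(0L, 1L, 2L, 0L), c(1L, 2L, 0L)), v1)
  tr2 <- as_corpus(list(c(0L, 1L, 2L, 0L), c(1L, 2L, 0L)), v2)
  cfg <- tiny_fm_config(max_steps = 20L, patience = 10L)
  parent <- pretrainFM(tr1, tr1, v1, cfg, seed = 1, site = "X")
  expect_error(continuePretrainFM(parent, tr2, tr2, cfg, seed = 1),
               "vocabulary mismatch")
})

test_that("frozen representations are deterministic and respect slicing", {
  tl <- small_pop()
  v <- buildVocabulary(tl, K = 128)
  corp <- tokenize(tl, v)
  cfg <- tiny_fm_config(max_steps = 60L, patience = 40L)
  ck <- pretrainFM(corp, corp, v, cfg, seed = 6, site = "A")
  ex <- data.frame(patient_id = persons(tl)$patient_id[1:6],
                   prediction_time = max(events(tl)$time) + 1)
  r1 <- extractRepresentations(ck, ex, tl)
  r2 <- extractRepresentations(ck, ex, tl)
  expect_identical(r1, r2)
  # appending an event at/after prediction time changes nothing
  ev2 <- rbind(events(tl),
               data.frame(patient_id = ex$patient_id[1],
                          time = ex$prediction_time[1] + 5,
                          code = "DX/001", value = NA_real_))
  tl2 <- timelineSet(persons(tl), ev2, admissions(tl))
  r3 <- extractRepresentations(ck, ex, tl2)
  expect_equal(r1, r3, tolerance = 1e-12)
  # empty history -> zero vector
  ex0 <- data.frame(patient_id = ex$patient_id[1],
                    prediction_time = min(events(tl)$time) - 10)
  expect_equal(as.numeric(extractRepresentations(ck, ex0, tl)),
               rep(0, cfg$hidden_size))
})

test_that("patients in different latent states get different representations", {
  cfg_s <- synthConfig(n_patients_per_site = 120L)
  tl <- generateSitePopulation(cfg_s, "B", seed = 21)
  v <- buildVocabulary(tl, K = 128)
  corp <- tokenize(tl, v)
  ck <- pretrainFM(corp, corp, v, tiny_fm_config(max_steps = 60L,
                                                 patience = 40L),
                   seed = 7, site = "B")
  adm <- admissions(tl)
  # contrast a long-stay (sick) patient with a short-stay one
  los <- adm$discharge_time - adm$admit_time
  p_sick <- adm$patient_id[which.max(los)]
  p_well <- adm$patient_id[which.min(los)]
  t_end <- max(events(tl)$time) + 1
  ex <- data.frame(patient_id = c(p_sick, p_well), prediction_time = t_end)
  r <- extractRepresentations(ck, ex, tl)
  expect_gt(sqrt(sum((r[1, ] - r[2, ])^2)), 0)
})

test_that("checkpoints round-trip through the on-disk format", {
  v <- make_vocab(paste0("S", 1:3))
  tr <- as_corpus(markovCorpus(diag(3) * 0 + 1 / 3, 10, 30, seed = 2), v)
  cfg <- tiny_fm_config(max_steps = 30L, patience = 20L)
  ck <- pretrainFM(tr, tr, v, cfg, seed = 1, site = "X")
  d <- file.path(tempdir(), "ckpt")
  saveCheckpoint(ck, d)
  ck2 <- loadCheckpoint(d)
  expect_equal(ck2@params, ck@params, tolerance = 1e-12)
  expect_identical(vocabCodes(fmVocabulary(ck2)), vocabCodes(ck@vocabulary))
  expect_equal(fmValidationLoss(ck2, tr), fmValidationLoss(ck, tr),
               tolerance = 1e-10)
})
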