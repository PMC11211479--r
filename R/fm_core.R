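# Miniature structured-EHR foundation model: vocabulary, tokenizer, and the
# training/extraction API over the compiled decoder-only local-attention
# transformer (see src/transformer.cpp).

#' Foundation-model configuration
#'
#' Architecture and optimization settings for the miniature next-code
#' transformer. Defaults are desk-scale: 2 layers, hidden size 64, 4
#' heads, causal sliding-window attention of width 64, sequences chunked
#' to 128 tokens. A "step" is one Adam update over a batch assembled to a
#' fixed token budget; early stopping halts training when validation loss
#' has not improved for `patience` steps, and the best-validation
#' parameters are returned. The learning rate is tuned over
#' `lr_candidates` by validation loss.
#'
#' @param n_layers transformer layers.
#' @param hidden_size embedding/hidden width.
#' @param n_heads attention heads (must divide `hidden_size`).
#' @param attn_window causal local-attention window (tokens).
#' @param max_seq_len maximum tokens per training chunk / input history.
#' @param lr_candidates learning rates tried; best validation loss wins.
#' @param batch_tokens token budget per optimizer step.
#' @param max_steps maximum optimizer steps.
#' @param eval_every validation-loss evaluation cadence (steps).
#' @param patience early-stop patience in steps.
#' @param grad_clip global gradient-norm clip (0 disables).
#' @param representation `"last"` (final-layer hidden state at the last
#'   token) or `"mean"` (mean over positions).
#' @param seed RNG seed for initialization and batch sampling.
#' @return named list of class `fm_config`.
#' @export
fmConfig <- function(n_layers = 2L, hidden_size = 64L, n_heads = 4L,
                     attn_window = 64L, max_seq_len = 128L,
                     lr_candidates = c(1e-3, 3e-4, 1e-4),
                     batch_tokens = 1024L, max_steps = 2000L,
                     eval_every = 25L, patience = 500L, grad_clip = 1,
                     representation = c("last", "mean"), seed = 1L) {
  representation <- match.arg(representation)
  cfg <- list(n_layers = as.integer(n_layers),
              hidden_size = as.integer(hidden_size),
              n_heads = as.integer(n_heads),
              attn_window = as.integer(attn_window),
              max_seq_len = as.integer(max_seq_len),
              lr_candidates = as.numeric(lr_candidates),
              batch_tokens = as.integer(batch_tokens),
              max_steps = as.integer(max_steps),
              eval_every = as.integer(eval_every),
              patience = as.integer(patience),
              grad_clip = grad_clip,
              representation = representation,
              seed = as.integer(seed))
  stopifnot(cfg$n_layers >= 1, cfg$hidden_size >= 1, cfg$n_heads >= 1,
            cfg$hidden_size %% cfg$n_heads == 0, cfg$attn_window >= 1,
            cfg$max_seq_len >= 2, length(cfg$lr_candidates) >= 1,
            cfg$patience < cfg$max_steps || cfg$max_steps == 0)
  class(cfg) <- "fm_config"
  cfg
}

#' Build a frequency-ranked vocabulary
#'
#' Ranks codes by total occurrence count in the corpus (descending, ties
#' broken lexicographically by code string) and keeps the top `K`. Codes
#' outside the vocabulary are dropped at tokenization time. The full-scale
#' reference model uses K = 65536; desk-scale corpora need far less.
#'
#' @param x a [TimelineSet-class], or a character vector of codes.
#' @param K maximum vocabulary size.
#' @return a [Vocabulary-class].
#' @export
buildVocabulary <- function(x, K = 65536L) {
  if (K < 1) stop("K must be at least 1")
  codes <- if (is(x, "TimelineSet")) events(x)$code else as.character(x)
  if (!length(codes)) stop("empty corpus")
  tab <- table(codes)
  ord <- order(-as.numeric(tab), names(tab), method = "radix")
  keep <- ord[seq_len(min(K, length(ord)))]
  new("Vocabulary", codes = names(tab)[keep],
      counts = as.numeric(tab)[keep], maxSize = as.integer(K))
}

#' Tokenize timelines against a vocabulary
#'
#' Maps each patient's time-ordered code sequence to 0-based token indices,
#' dropping out-of-vocabulary codes while preserving order, and recording
#' per-token timestamps and the dropped-code count. The returned list
#' carries the vocabulary's code list as an attribute so downstream
#' continued pretraining can verify vocabulary identity.
#'
#' @param timelines a [TimelineSet-class].
#' @param vocab a [Vocabulary-class].
#' @return named list (one element per patient) of lists with `tokens`
#'   (integer, 0-based), `times`, `dropped`; attribute `vocab_codes`.
#' @export
tokenize <- function(timelines, vocab) {
  stopifnot(is(timelines, "TimelineSet"), is(vocab, "Vocabulary"))
  ev <- events(timelines)
  idx <- match(ev$code, vocab@codes) - 1L   # 0-based; NA = OOV
  out <- lapply(split(seq_len(nrow(ev)), ev$patient_id), function(ix) {
    tok <- idx[ix]
    ok <- !is.na(tok)
    list(tokens = as.integer(tok[ok]), times = ev$time[ix][ok],
         dropped = sum(!ok))
  })
  # patients with zero events still get an entry
  missing <- setdiff(persons(timelines)$patient_id, names(out))
  if (length(missing)) {
    extra <- lapply(missing, function(p)
      list(tokens = integer(), times = numeric(), dropped = 0L))
    names(extra) <- missing
    out <- c(out, extra)
  }
  out <- out[order(names(out), method = "radix")]
  attr(out, "vocab_codes") <- vocab@codes
  out
}

# chunk tokenized timelines into training sequences of <= max_len tokens
.chunk_sequences <- function(tokenized, max_len) {
  seqs <- list()
  for (tl in tokenized) {
    tok <- tl$tokens
    n <- length(tok)
    if (n < 2) next
    starts <- seq(1L, n, by = max_len)
    for (s in starts) {
      chunk <- tok[s:min(n, s + max_len - 1L)]
      if (length(chunk) >= 2) seqs[[length(seqs) + 1L]] <- chunk
    }
  }
  seqs
}

.cpp_cfg <- function(config, vocab_size, lr, seed) {
  list(vocab_size = as.integer(vocab_size),
       max_seq_len = config$max_seq_len, hidden_size = config$hidden_size,
       n_layers = config$n_layers, n_heads = config$n_heads,
       attn_window = config$attn_window, lr = lr,
       grad_clip = config$grad_clip, batch_tokens = config$batch_tokens,
       max_steps = config$max_steps, eval_every = config$eval_every,
       patience = config$patience, seed = as.integer(seed))
}

.check_vocab_match <- function(corpus, vocab) {
  vc <- attr(corpus, "vocab_codes")
  if (!is.null(vc) && !identical(vc, vocab@codes)) {
    stop("vocabulary mismatch: corpus was tokenized with a different vocabulary")
  }
}

.train_fm <- function(init_params, trainSeqs, validSeqs, vocab, config, seed,
                      provenance) {
  chunks_tr <- .chunk_sequences(trainSeqs, config$max_seq_len)
  chunks_va <- .chunk_sequences(validSeqs, config$max_seq_len)
  if (!length(chunks_tr)) stop("empty training corpus after tokenization")
  if (!length(chunks_va)) stop("empty validation corpus after tokenization")
  best <- NULL
  for (lr in config$lr_candidates) {
    cc <- .cpp_cfg(config, length(vocab@codes), lr, seed)
    p0 <- if (is.null(init_params)) .cpp_fm_init(cc) else init_params
    fit <- .cpp_fm_train(p0, chunks_tr, chunks_va, cc)
    fit$lr <- lr
    if (is.null(best) || fit$valid_loss < best$valid_loss) best <- fit
  }
  provenance$steps <- best$steps
  provenance$best_step <- best$best_step
  provenance$valid_loss <- best$valid_loss
  provenance$learning_rate <- best$lr
  ck <- new("FMCheckpoint", params = best$params, vocabulary = vocab,
            config = unclass(config), provenance = provenance)
  attr(ck, "history") <- best$history
  ck
}

#' Pretrain a foundation model from scratch
#'
#' Minimizes mean next-token cross-entropy with causal masking over the
#' tokenized training corpus, evaluating on the validation corpus for
#' learning-rate selection and early stopping, and returns the
#' best-validation checkpoint. Sequences longer than the configured
#' maximum are chunked; sequences shorter than 2 tokens are dropped.
#'
#' @param trainSeqs,validSeqs tokenized corpora from [tokenize()].
#' @param vocab the [Vocabulary-class] used for tokenization.
#' @param config an [fmConfig()].
#' @param seed RNG seed (initialization + batch order).
#' @param site site label recorded in provenance.
#' @return an [FMCheckpoint-class].
#' @export
pretrainFM <- function(trainSeqs, validSeqs, vocab, config = fmConfig(),
                       seed = config$seed, site = "unknown") {
  .check_vocab_match(trainSeqs, vocab)
  .check_vocab_match(validSeqs, vocab)
  .train_fm(NULL, trainSeqs, validSeqs, vocab, config, seed,
            list(kind = "from_scratch", site = site))
}

#' Continue pretraining from a parent checkpoint
#'
#' Resumes the next-code objective from the parent's parameters on a new
#' corpus tokenized with the parent's vocabulary (which is inherited,
#' never rebuilt). The optimizer state restarts; the learning rate is
#' selected from the config candidates by validation loss; early stopping
#' matches [pretrainFM()]. Provenance records the parent site.
#'
#' @param parent an [FMCheckpoint-class].
#' @param trainSeqs,validSeqs corpora tokenized with the parent vocabulary.
#' @param config an [fmConfig()]; defaults to the parent's config.
#' @param seed RNG seed.
#' @param site site label of the adaptation corpus.
#' @return an [FMCheckpoint-class] with `kind = "continued"`.
#' @export
continuePretrainFM <- function(parent, trainSeqs, validSeqs, config = NULL,
                               seed = NULL, site = "unknown") {
  stopifnot(is(parent, "FMCheckpoint"))
  if (is.null(config)) {
    config <- parent@config
    class(config) <- "fm_config"
  }
  if (is.null(seed)) seed <- config$seed
  vocab <- parent@vocabulary
  vc <- attr(trainSeqs, "vocab_codes")
  if (is.null(vc) || !identical(vc, vocab@codes)) {
    stop("vocabulary mismatch: continued pretraining requires the parent vocabulary")
  }
  .check_vocab_match(validSeqs, vocab)
  if (config$max_steps == 0) {
    prov <- list(kind = "continued", site = site,
                 parent_site = parent@provenance$site, steps = 0L,
                 best_step = 0L, valid_loss = NA_real_,
                 learning_rate = NA_real_)
    return(new("FMCheckpoint", params = parent@params, vocabulary = vocab,
               config = unclass(config), provenance = prov))
  }
  .train_fm(parent@params, trainSeqs, validSeqs, vocab, config, seed,
            list(kind = "continued", site = site,
                 parent_site = parent@provenance$site))
}

#' Evaluate mean next-code cross-entropy of a checkpoint
#'
#' @param checkpoint an [FMCheckpoint-class].
#' @param seqs tokenized corpus from [tokenize()].
#' @return mean per-token cross-entropy (nats).
#' @export
fmValidationLoss <- function(checkpoint, seqs) {
  .check_vocab_match(seqs, checkpoint@vocabulary)
  config <- checkpoint@config
  chunks <- .chunk_sequences(seqs, config$max_seq_len)
  cc <- .cpp_cfg(config, length(checkpoint@vocabulary@codes),
                 config$lr_candidates[1], config$seed)
  .cpp_fm_loss(checkpoint@params, chunks, cc)
}

#' Extract frozen-encoder representations
#'
#' Uses the checkpoint as a frozen feature encoder: for each example, the
#' patient's history is sliced strictly before the prediction time,
#' tokenized with the checkpoint vocabulary, truncated to the most recent
#' `max_seq_len` tokens, and encoded; the representation is the
#' final-layer hidden state at the last token (or the mean over positions
#' when the config says so). Examples with empty tokenized history get the
#' zero vector. Deterministic given the checkpoint.
#'
#' @param checkpoint an [FMCheckpoint-class].
#' @param examples data.frame with `patient_id` and `prediction_time`.
#' @param timelines the [TimelineSet-class] holding full histories.
#' @return numeric matrix, one row per example, `hidden_size` columns.
#' @export
extractRepresentations <- function(checkpoint, examples, timelines) {
  stopifnot(is(checkpoint, "FMCheckpoint"),
            all(c("patient_id", "prediction_time") %in% names(examples)))
  config <- checkpoint@config
  vocab <- checkpoint@vocabulary
  ev <- events(timelines)
  idx <- match(ev$code, vocab@codes) - 1L
  ev_ix_by_pat <- split(seq_len(nrow(ev)), ev$patient_id)
  cc <- .cpp_cfg(config, length(vocab@codes), config$lr_candidates[1],
                 config$seed)
  key <- paste(examples$patient_id, examples$prediction_time)
  uk <- !duplicated(key)
  reps <- matrix(0, nrow = sum(uk), ncol = config$hidden_size)
  ukey <- key[uk]
  upat <- examples$patient_id[uk]
  upred <- examples$prediction_time[uk]
  for (i in seq_along(ukey)) {
    ix <- ev_ix_by_pat[[upat[i]]]
    if (is.null(ix)) next
    ix <- ix[ev$time[ix] < upred[i]]
    tok <- idx[ix]
    tok <- tok[!is.na(tok)]
    n <- length(tok)
    if (n == 0) next
    if (n > config$max_seq_len) tok <- tok[(n - config$max_seq_len + 1L):n]
    h <- .cpp_fm_hidden(checkpoint@params, as.integer(tok), cc)
    reps[i, ] <- if (config$representation == "mean") colMeans(h)
                 else h[nrow(h), ]
  }
  out <- reps[match(key, ukey), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- checkpoint persistence -------------------------------------------------

#' Save / load a checkpoint directory
#'
#' A checkpoint directory holds the parameter matrices (one CSV blob),
#' the vocabulary (`vocabulary.txt`: code, rank, count per line) and a
#' JSON manifest with the config and training provenance.
#'
#' @param checkpoint an [FMCheckpoint-class].
#' @param dir directory path.
#' @return `saveCheckpoint`: `dir` invisibly; `loadCheckpoint`: the
#'   restored [FMCheckpoint-class].
#' @export
saveCheckpoint <- function(checkpoint, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vb <- checkpoint@vocabulary
  utils::write.table(
    data.frame(code = vb@codes, rank = seq_along(vb@codes),
               count = vb@counts),
    file.path(dir, "vocabulary.txt"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  jsonlite::write_json(list(config = checkpoint@config,
                            provenance = checkpoint@provenance,
                            vocab_max_size = vb@maxSize),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  shapes <- lapply(checkpoint@params, dim)
  jsonlite::write_json(shapes, file.path(dir, "shapes.json"))
  flat <- unlist(lapply(checkpoint@params, as.numeric))
  data.table::fwrite(data.table::data.table(v = flat),
                     file.path(dir, "params.csv"))
  invisible(dir)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  vt <- utils::read.table(file.path(dir, "vocabulary.txt"), sep = "\t",
                          header = TRUE, colClasses = c("character",
                                                        "integer", "numeric"))
  vocab <- new("Vocabulary", codes = vt$code, counts = vt$count,
               maxSize = as.integer(man$vocab_max_size))
  shapes <- jsonlite::read_json(file.path(dir, "shapes.json"),
                                simplifyVector = TRUE)
  flat <- data.table::fread(file.path(dir, "params.csv"))$v
  params <- list()
  off <- 0L
  for (nm in names(shapes)) {
    sh <- shapes[[nm]]
    k <- sh[1] * sh[2]
    params[[nm]] <- matrix(flat[(off + 1):(off + k)], nrow = sh[1])
    off <- off + k
  }
  cfg <- man$config
  new("FMCheckpoint", params = params, vocabulary = vocab, config = cfg,
      provenance = man$provenance)
}

# ---- Markov-chain corpus utilities (oracles for pretraining tests) ---------

#' First-order Markov code corpora with closed-form entropies
#'
#' `markovCorpus()` simulates token sequences from a first-order Markov
#' chain (started from its stationary distribution);
#' `markovEntropies()` returns the chain's unigram entropy (entropy of the
#' stationary marginal) and conditional next-token entropy, in nats. The
#' conditional entropy is the converged cross-entropy an ideal next-code
#' model attains on such a corpus; the unigram entropy is what a
#' context-free model attains — together they sandwich any competent
#' autoregressive fit.
#'
#' @param transition row-stochastic transition matrix.
#' @param n_seqs,len number and length of sequences.
#' @param seed RNG seed.
#' @return `markovCorpus`: list of 0-based integer token sequences;
#'   `markovEntropies`: list with `unigram`, `conditional` (nats).
#' @export
markovCorpus <- function(transition, n_seqs = 64L, len = 64L, seed = 1L) {
  k <- nrow(transition)
  stopifnot(ncol(transition) == k, all(abs(rowSums(transition) - 1) < 1e-9))
  pi0 <- .stationary_dist(transition)
  .run_seeded(seed, {
    lapply(seq_len(n_seqs), function(i) {
      s <- integer(len)
      s[1] <- sample.int(k, 1, prob = pi0)
      for (t in 2:len) s[t] <- sample.int(k, 1, prob = transition[s[t - 1], ])
      s - 1L
    })
  })
}

#' @rdname markovCorpus
#' @export
markovEntropies <- function(transition) {
  pi0 <- .stationary_dist(transition)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  list(unigram = ent(pi0),
       conditional = sum(pi0 * apply(transition, 1, ent)))
}

.stationary_dist <- function(Tm) {
  e <- eigen(t(Tm))
  v <- abs(Re(e$vectors[, which.min(abs(e$values - 1))]))
  v / sum(v)
}
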