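# Two-site synthetic EHR generator. Patients carry a day-granular latent
# health state (first-order Markov). Each admitted day the state emits
# Poisson-many coded events from a site-tilted categorical distribution and
# state-dependent Gaussian lab values; the stay terminates through
# state-dependent discharge/death hazards applied at day end; discharged
# patients may be readmitted within 30 days with a probability depending on
# their last state. Outcomes are emergent (lab values crossing clinical
# thresholds, hazards), never painted-on labels, so the cohort labelling
# code is the single source of truth. The first-order structure gives
# closed-form oracles (analytic task rates, code marginals, entropies) used
# by the test suite.

.run_seeded <- function(seed, expr) {
  env <- parent.frame()
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval(expr, env)
}

.check_prob_vec <- function(x, what) {
  if (any(x < 0) || abs(sum(x) - 1) > 1e-9) {
    stop("config validation error: ", what, " is not a probability vector")
  }
}

.lab_defaults <- function(n_states) {
  # per-lab: threshold/direction as in the eight clinical tasks; means per
  # latent state chosen so crossings concentrate in the sicker states
  # threshold crossings concentrate almost entirely in the critical state,
  # so abnormal-lab outcomes track the latent trajectory sharply
  labs <- list(
    "LAB/GLU" = list(sd = 0.55, mu = c(5.5, 5.3, 5.0, 3.7)),
    "LAB/NA"  = list(sd = 2.2,  mu = c(140, 138, 136, 128.5)),
    "LAB/K"   = list(sd = 0.5,  mu = c(4.1, 4.3, 4.6, 6.1)),
    "LAB/HGB" = list(sd = 8,    mu = c(125, 116, 105, 82)),
    "LAB/PLT" = list(sd = 22,   mu = c(250, 205, 150, 80)),
    "LAB/CRP" = list(sd = 20,   mu = c(5, 20, 60, 120)))
  lambda <- rbind(
    "LAB/GLU" = c(0.5, 0.7, 1.0, 1.5),
    "LAB/NA"  = c(0.5, 0.7, 1.0, 1.5),
    "LAB/K"   = c(0.5, 0.7, 1.0, 1.5),
    "LAB/HGB" = c(0.6, 0.8, 1.0, 1.5),
    "LAB/PLT" = c(0.6, 0.8, 1.0, 1.5),
    "LAB/CRP" = c(0.3, 0.8, 1.5, 2.0))
  mu <- do.call(rbind, lapply(labs, `[[`, "mu"))
  sd <- vapply(labs, `[[`, numeric(1), "sd")
  idx <- seq_len(n_states)
  # replicate last column when fewer states than 4 are configured
  idx <- pmin(idx, ncol(mu))
  list(codes = names(labs), mu = mu[, idx, drop = FALSE],
       lambda = lambda[, idx, drop = FALSE], sd = sd)
}

#' Synthetic two-site EHR configuration
#'
#' Builds the configuration driving [generateSitePopulation()]: the latent
#' patient-state model (initial distribution per site, daily transition
#' matrix, per-state event rates, lab-value distributions, discharge/death
#' hazards, readmission probabilities) and the two site profiles
#' (population size, age distribution, code-vocabulary subset and frequency
#' tilt). Site A emulates a pediatric hospital, site B a sicker adult
#' hospital: they share a core code vocabulary (>= 80% of each site's
#' codes) but differ in code frequencies and in initial-state mix, so the
#' sites exhibit a material distribution shift while remaining mutually
#' intelligible — the precondition for cross-site transfer experiments.
#'
#' @param seed default RNG seed used by the generator.
#' @param n_patients_per_site patients per site (default 2000).
#' @param n_states number of latent states (default 4, healthy to critical).
#' @param n_shared_codes,n_site_codes non-lab codes shared by both sites and
#'   exclusive to each site.
#' @param site_tilt log-scale frequency tilt applied with opposite signs at
#'   the two sites (coding-practice shift).
#' @param block_weight emission weight multiplier tying each code block to
#'   its latent state (signal strength for next-code pretraining).
#' @param overrides named list merged over the constructed config (advanced).
#' @return validated config list (class `synth_config`).
#' @export
synthConfig <- function(seed = 1L, n_patients_per_site = 2000L,
                        n_states = 4L, n_shared_codes = 72L,
                        n_site_codes = 18L, site_tilt = 0.6,
                        block_weight = 10, overrides = list()) {
  s4 <- function(x) x[pmin(seq_len(n_states), length(x))]
  cfg <- list(
    seed = as.integer(seed),
    n_states = as.integer(n_states),
    transition = .default_transition(n_states),
    discharge_hazard = s4(c(0.50, 0.28, 0.08, 0.015)),
    death_hazard = s4(c(0.0002, 0.001, 0.006, 0.05)),
    event_rate = s4(c(4, 6, 9, 14)),
    readmit_prob = s4(c(0.01, 0.04, 0.15, 0.35)),
    readmit_gap_days = c(3L, 25L),
    max_los_days = 60L,
    day0_fraction = 0.5,
    pre_events_mean = 24,
    pre_window_days = 180L,
    labs = .lab_defaults(n_states),
    vocab = list(n_shared = as.integer(n_shared_codes),
                 n_site = as.integer(n_site_codes),
                 tilt = site_tilt, block_weight = block_weight),
    sites = list(
      A = list(site_id = "A", n_patients = as.integer(n_patients_per_site),
               initial_dist = s4(c(0.55, 0.28, 0.13, 0.04)) /
                 sum(s4(c(0.55, 0.28, 0.13, 0.04))),
               age_days_range = c(180, 17 * 365), min_age_days = 28,
               tilt_sign = +1),
      B = list(site_id = "B", n_patients = as.integer(n_patients_per_site),
               initial_dist = s4(c(0.20, 0.26, 0.32, 0.22)) /
                 sum(s4(c(0.20, 0.26, 0.32, 0.22))),
               age_days_range = c(19 * 365, 85 * 365),
               min_age_days = 18 * 365, tilt_sign = -1)))
  cfg <- modifyList(cfg, overrides)
  class(cfg) <- "synth_config"
  validateSynthConfig(cfg)
  cfg
}

.default_transition <- function(n_states) {
  # sticky chain: a patient's admission-day state strongly shapes the rest
  # of the stay, as chronic severity does in real inpatient populations
  full <- rbind(c(0.92, 0.06, 0.017, 0.003),
                c(0.12, 0.76, 0.11, 0.01),
                c(0.03, 0.14, 0.80, 0.03),
                c(0.01, 0.04, 0.25, 0.70))
  if (n_states == 4L) return(full)
  m <- full[seq_len(n_states), seq_len(n_states), drop = FALSE]
  sweep(m, 1, rowSums(m), "/")
}

#' Validate a synthetic-EHR config
#'
#' Checks probability vectors (sum to 1 within 1e-9), row-stochastic
#' transition matrix, hazards in \[0, 1\] and structural fields. Called by
#' [synthConfig()]; exported so hand-edited configs read from YAML can be
#' revalidated.
#'
#' @param config a `synth_config` list.
#' @return `config`, invisibly; errors on invalid input.
#' @export
validateSynthConfig <- function(config) {
  k <- config$n_states
  stopifnot(k >= 1L)
  if (!is.matrix(config$transition) || any(dim(config$transition) != k)) {
    stop("config validation error: transition must be ", k, "x", k)
  }
  for (i in seq_len(k)) {
    .check_prob_vec(config$transition[i, ], paste0("transition row ", i))
  }
  for (h in c("discharge_hazard", "death_hazard", "readmit_prob")) {
    v <- config[[h]]
    if (length(v) != k || any(v < 0 | v > 1)) {
      stop("config validation error: ", h, " must be ", k, " values in [0,1]")
    }
  }
  for (sn in names(config$sites)) {
    .check_prob_vec(config$sites[[sn]]$initial_dist,
                    paste0("initial_dist of site ", sn))
  }
  stopifnot(length(config$event_rate) == k, all(config$event_rate > 0))
  invisible(config)
}

#' @rdname synthConfig
#' @param path file path for YAML round-trip of a config.
#' @export
writeSynthConfig <- function(config, path) {
  cfg <- unclass(config)
  cfg$transition <- as.list(as.data.frame(t(cfg$transition)))
  cfg$labs$mu <- as.list(as.data.frame(t(cfg$labs$mu)))
  cfg$labs$lambda <- as.list(as.data.frame(t(cfg$labs$lambda)))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname synthConfig
#' @export
readSynthConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$transition <- unname(do.call(rbind, lapply(cfg$transition,
                                                 function(v) unname(unlist(v)))))
  mu <- do.call(rbind, lapply(cfg$labs$mu, function(v) unname(unlist(v))))
  la <- do.call(rbind, lapply(cfg$labs$lambda,
                              function(v) unname(unlist(v))))
  dimnames(mu) <- dimnames(la) <- list(unlist(cfg$labs$codes), NULL)
  cfg$labs$mu <- mu
  cfg$labs$lambda <- la
  cfg$labs$sd <- unlist(cfg$labs$sd)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "synth_config"
  validateSynthConfig(cfg)
  cfg
}

# ---- emission model ---------------------------------------------------------

.site_codes <- function(config, site_id) {
  v <- config$vocab
  shared <- sprintf("DX/%03d", seq_len(v$n_shared))
  own <- if (v$n_site > 0) sprintf("%s/%02d", site_id, seq_len(v$n_site))
         else character()
  list(shared = shared, own = own, all = c(shared, own))
}

# per-state categorical over the site's non-lab codes; rows = states
.emission_matrix <- function(config, site_id) {
  v <- config$vocab
  k <- config$n_states
  sc <- .site_codes(config, site_id)
  tilt_sign <- config$sites[[site_id]]$tilt_sign
  n_sh <- v$n_shared
  blk_shared <- ((seq_len(n_sh) - 1) %/% max(1, ceiling(n_sh / k))) + 1
  w_shared <- 1 / (5 + ((seq_len(n_sh) - 1) %% max(1, ceiling(n_sh / k))))
  w_shared <- w_shared * exp(tilt_sign * v$tilt * ifelse(seq_len(n_sh) %% 2 == 0, 1, -1))
  # site-exclusive codes are state-neutral (administrative/coding-practice
  # codes): they shift the marginal between sites without carrying
  # patient-state signal, so cross-site OOV drops cost little information
  n_own <- length(sc$own)
  w_own <- if (n_own) 0.5 / (4 + ((seq_len(n_own) - 1) %/% k)) else numeric()
  blk <- c(blk_shared, rep(0L, n_own))   # block 0 = no state affinity
  w <- c(w_shared, w_own)
  em <- matrix(0, nrow = k, ncol = length(w),
               dimnames = list(NULL, sc$all))
  for (s in seq_len(k)) {
    ws <- w * ifelse(blk == s, v$block_weight, 1)
    em[s, ] <- ws / sum(ws)
  }
  em
}

# combined per-state distribution over all emitted codes (non-lab + lab),
# weighting by per-day rates; used for entropies and marginals
.state_code_dist <- function(config, site_id) {
  em <- .emission_matrix(config, site_id)
  k <- config$n_states
  lab <- config$labs
  rate_nonlab <- config$event_rate
  rate_lab <- colSums(lab$lambda)  # per state
  total <- rate_nonlab + rate_lab
  out <- matrix(0, nrow = k, ncol = ncol(em) + length(lab$codes),
                dimnames = list(NULL, c(colnames(em), lab$codes)))
  for (s in seq_len(k)) {
    out[s, colnames(em)] <- em[s, ] * rate_nonlab[s] / total[s]
    out[s, lab$codes] <- lab$lambda[, s] / total[s]
  }
  list(dist = out, total_rate = total)
}

# ---- analytic oracles -------------------------------------------------------

# in-hospital day-state occupancy vector over days 0..max, conditional on
# nothing (joint probabilities of being in hospital on day d in state s)
.day_state_occupancy <- function(config, site_id) {
  k <- config$n_states
  pi0 <- config$sites[[site_id]]$initial_dist
  hd <- config$death_hazard
  hc <- config$discharge_hazard
  Tm <- config$transition
  days <- config$max_los_days
  occ <- matrix(0, nrow = days + 1, ncol = k)
  occ[1, ] <- pi0
  for (d in seq_len(days)) {
    stay <- occ[d, ] * (1 - hd) * (1 - hc)
    occ[d + 1, ] <- as.numeric(stay %*% Tm)
  }
  occ
}

# expected number of emitted events per patient attributable to each
# latent state, accounting for the pre-admission outpatient history (all
# from the initial state), the half-day admission day, and the expected
# number of admissions per patient (readmissions share the admission law)
.event_state_weights <- function(config, site_id) {
  scd <- .state_code_dist(config, site_id)
  occ <- .day_state_occupancy(config, site_id)
  k <- config$n_states
  pi0 <- config$sites[[site_id]]$initial_dist
  hd <- config$death_hazard; hc <- config$discharge_hazard
  Tm <- config$transition
  hosp <- occ[1, ] * scd$total_rate * config$day0_fraction
  if (nrow(occ) > 1) {
    hosp <- hosp + colSums(occ[-1, , drop = FALSE] *
                             rep(scd$total_rate, each = nrow(occ) - 1))
  }
  # per-state expected event counts; `pre` covers the outpatient history,
  # which emits non-lab codes only
  # probability an admission ends in alive discharge and seeds a readmission
  cur <- pi0; r <- 0
  for (d in 0:config$max_los_days) {
    last <- d == config$max_los_days
    dis <- cur * (1 - hd) * hc
    stay <- cur * (1 - hd) * (1 - hc)
    if (last) { dis <- dis + stay; stay <- stay * 0 }
    r <- r + sum(dis * config$readmit_prob)
    cur <- as.numeric(stay %*% Tm)
  }
  pre <- config$pre_events_mean * pi0
  list(pre = pre, hosp = (1 + r) * hosp)
}

#' Analytic code marginals and entropies of the generator
#'
#' Computes, by iterating the latent Markov chain, the exact marginal
#' distribution over emitted codes at a site (`analyticCodeMarginals`), and
#' the unigram entropy together with the conditional entropy of a code
#' given the latent state (`analyticEntropies`), both in nats. Weights
#' account for the pre-admission outpatient history, the partial admission
#' day, and readmissions. The conditional entropy is a lower bound on what
#' next-code pretraining can achieve while the unigram entropy is the
#' no-context ceiling; their gap guarantees pretraining has learnable
#' signal.
#'
#' @param config a `synth_config`.
#' @param site_id "A" or "B".
#' @return `analyticCodeMarginals`: named probability vector over codes.
#'   `analyticEntropies`: list with `unigram`, `conditional` (nats).
#' @export
analyticCodeMarginals <- function(config, site_id) {
  scd <- .state_code_dist(config, site_id)
  em <- .emission_matrix(config, site_id)
  w <- .event_state_weights(config, site_id)
  m <- as.numeric(w$hosp %*% scd$dist)
  names(m) <- colnames(scd$dist)
  m[colnames(em)] <- m[colnames(em)] + as.numeric(w$pre %*% em)
  m / sum(m)
}

#' @rdname analyticCodeMarginals
#' @export
analyticEntropies <- function(config, site_id) {
  scd <- .state_code_dist(config, site_id)
  em <- .emission_matrix(config, site_id)
  w <- .event_state_weights(config, site_id)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  total <- sum(w$pre) + sum(w$hosp)
  cond <- (sum(w$pre * apply(em, 1, ent)) +
             sum(w$hosp * apply(scd$dist, 1, ent))) / total
  uni <- ent(analyticCodeMarginals(config, site_id))
  list(unigram = uni, conditional = cond)
}

#' Total variation distance between two discrete distributions
#'
#' @param p,q named probability vectors (codes missing from one are 0).
#' @return TV distance in \[0, 1\].
#' @export
tvDistance <- function(p, q) {
  codes <- union(names(p), names(q))
  pv <- ifelse(codes %in% names(p), p[codes], 0)
  qv <- ifelse(codes %in% names(q), q[codes], 0)
  pv[is.na(pv)] <- 0; qv[is.na(qv)] <- 0
  0.5 * sum(abs(pv - qv))
}

# per-day probability that at least one qualifying lab crossing is emitted,
# per state (Poisson thinning of the lab emission by the tail probability of
# the value distribution beyond the clinical threshold)
.lab_cross_day <- function(config, code) {
  lab <- config$labs
  i <- match(code, lab$codes)
  mu <- lab$mu[i, ]; sd <- lab$sd[i]
  thr <- switch(code, "LAB/GLU" = 3, "LAB/NA" = 125, "LAB/K" = 7,
                "LAB/HGB" = 70, "LAB/PLT" = 50,
                stop("no threshold for ", code))
  q <- if (code == "LAB/K") 1 - stats::pnorm((thr - mu) / sd)
       else stats::pnorm((thr - mu) / sd)
  list(full = 1 - exp(-lab$lambda[i, ] * q),
       day0 = 1 - exp(-config$day0_fraction * lab$lambda[i, ] * q))
}

# Exact path statistics of one generic admission for one task, by iterating
# the latent chain with hazards. Returns joint probabilities (with
# admission-eligibility where noted) of the admission being task-included
# with label 1 (`qI1`) / label 0 (`qI0`) or task-excluded (`qX`), split by
# whether a readmission follows (suffix R; death and non-readmitted
# discharge make up the complement). `label` is one of "death", "long_los",
# or a lab code; `cross` supplies crossing probabilities for lab labels.
.adm_task_stats <- function(config, site_id, label, cross = NULL) {
  k <- config$n_states
  pi0 <- config$sites[[site_id]]$initial_dist
  hd <- config$death_hazard; hc <- config$discharge_hazard
  Tm <- config$transition
  pre <- config$readmit_prob
  days <- config$max_los_days
  is_lab <- !(label %in% c("death", "long_los"))

  surv0 <- (1 - hd) * (1 - hc)
  # families tracked from day 1 (all joint with eligibility):
  if (is_lab) {
    fam_X <- pi0 * surv0 * cross$day0        # excluded: crossing on day 0
    fam_nc <- pi0 * surv0 * (1 - cross$day0) # included, not crossed yet
    fam_c <- numeric(k)                      # included, crossed (label 1)
    fam_X <- as.numeric(fam_X %*% Tm)
    fam_nc <- as.numeric(fam_nc %*% Tm)
  } else {
    fam_X <- numeric(k)
    fam_nc <- as.numeric((pi0 * surv0) %*% Tm)
    fam_c <- numeric(k)
  }
  acc <- list(X = list(die = 0, dis = numeric(k)),
              L1 = list(die = 0, dis = numeric(k)),
              L0 = list(die = 0, dis = numeric(k)))
  for (d in 1:days) {
    if (is_lab) {
      newly <- fam_nc * cross$full
      fam_nc <- fam_nc - newly
      fam_c <- fam_c + newly
    }
    last <- d == days
    for (f in c("X", "nc", "c")) {
      v <- switch(f, X = fam_X, nc = fam_nc, c = fam_c)
      die <- sum(v * hd)
      dis <- v * (1 - hd) * hc
      stay <- v * (1 - hd) * (1 - hc)
      if (last) { dis <- dis + stay; stay <- numeric(k) }  # forced discharge at cap
      g <- if (f == "X") "X" else if (is_lab) {
        if (f == "c") "L1" else "L0"
      } else if (label == "death") {
        # death paths are label 1, alive-discharge label 0
        NA_character_
      } else {  # long_los: label by end day
        if (d >= 7) "L1" else "L0"
      }
      if (label == "death") {
        acc$L1$die <- acc$L1$die + die
        acc$L0$dis <- acc$L0$dis + dis
      } else {
        acc[[g]]$die <- acc[[g]]$die + die
        acc[[g]]$dis <- acc[[g]]$dis + dis
      }
      v_new <- as.numeric(stay %*% Tm)
      if (f == "X") fam_X <- v_new else if (f == "nc") fam_nc <- v_new
      else fam_c <- v_new
    }
  }
  # long-LOS label 1 also includes deaths on days >= 7 (handled above via g);
  # death-label deaths carry no readmission; discharges may readmit
  tot <- function(g) acc[[g]]$die + sum(acc[[g]]$dis)
  withR <- function(g) sum(acc[[g]]$dis * pre)
  list(qI1 = tot("L1"), qI0 = tot("L0"), qX = tot("X"),
       qI1_R = withR("L1"), qI0_R = withR("L0"), qX_R = withR("X"),
       q_alive = sum(acc$L1$dis) + sum(acc$L0$dis) + sum(acc$X$dis),
       q_alive_R = withR("L1") + withR("L0") + withR("X"))
}

#' Analytic task outcome rates of the generator
#'
#' Computes, for one site, the exact prevalence each of the eight clinical
#' prediction tasks will have in the labeled inpatient cohort (after the
#' cohort's eligibility rule, the uniform one-admission-per-patient
#' selection, and the per-task exclusion rules), by brute-force iteration
#' of the latent Markov chain with its discharge/death hazards,
#' lab-crossing thinning probabilities and the readmission mechanism. The
#' selection step is enumerated exactly, including the dependence between
#' an admission's outcome and the presence of a readmission (which makes a
#' second admission available for selection). These are the oracle values
#' the empirical prevalences are tested against.
#'
#' @inheritParams analyticCodeMarginals
#' @return named numeric vector over the eight task names.
#' @export
analyticTaskRates <- function(config, site_id) {
  k <- config$n_states
  pi0 <- config$sites[[site_id]]$initial_dist
  hd <- config$death_hazard; hc <- config$discharge_hazard
  pre <- config$readmit_prob

  # day-0 terminations (ineligible admission) can still seed a readmission
  dis0 <- pi0 * (1 - hd) * hc
  p_nE1_R <- sum(dis0 * pre)
  p_E1 <- sum(pi0 * (1 - hd) * (1 - hc))
  e2 <- p_E1                                   # eligibility of admission 2
  p_cohort <- p_E1 + p_nE1_R * e2              # patient has >=1 eligible adm

  # generic admission-2 inclusion stats per task (same law, fresh initial
  # state, never readmits itself)
  task_rate <- function(label, cross = NULL) {
    st <- .adm_task_stats(config, site_id, label, cross)
    qI1_2 <- st$qI1; qI0_2 <- st$qI0            # admission-2 quantities
    p_E1_R <- st$qI1_R + st$qI0_R + st$qX_R     # adm1 eligible & readmitted
    # numerator / denominator of the task-cohort prevalence over patients
    N <- (st$qI1 - st$qI1_R) +                  # E1, no readmission
      st$qI1_R * (1 - e2) +                     # E1, R, adm2 ineligible
      0.5 * st$qI1_R * e2 +                     # E1, R, E2, adm1 selected
      0.5 * p_E1_R * e2 * (qI1_2 / e2) +        # E1, R, E2, adm2 selected
      p_nE1_R * qI1_2                           # !E1, R, adm2 selected
    D <- (st$qI1 + st$qI0 - st$qI1_R - st$qI0_R) +
      (st$qI1_R + st$qI0_R) * (1 - e2) +
      0.5 * (st$qI1_R + st$qI0_R) * e2 +
      0.5 * p_E1_R * e2 * ((qI1_2 + qI0_2) / e2) +
      p_nE1_R * (qI1_2 + qI0_2)
    N / D
  }

  # 30-day readmission: label 1 iff a later admission exists; in-hospital
  # deaths are excluded (the outcome window opens at discharge midnight and
  # death precedes it)
  st0 <- .adm_task_stats(config, site_id, "death")
  q_alive <- st0$q_alive; q_alive_R <- st0$q_alive_R
  q_alive2 <- q_alive                           # adm2: alive discharge
  N_re <- q_alive_R * (1 - e2) + 0.5 * q_alive_R * e2 + q_alive_R * 0
  # E1 & R: adm1 is alive by construction; selected adm1 w.p. 1 (no adm2
  # eligible) or 1/2; adm2 selections contribute label 0
  D_re <- (q_alive - q_alive_R) +               # E1, alive, no R
    q_alive_R * (1 - e2) + 0.5 * q_alive_R * e2 +
    0.5 * (st0$qI1_R + st0$qI0_R + st0$qX_R) * e2 * (q_alive2 / e2) +
    p_nE1_R * q_alive2
  readmit <- N_re / D_re

  c(mortality = task_rate("death"),
    long_los = task_rate("long_los"),
    readmission_30d = readmit,
    hypoglycemia = task_rate("LAB/GLU", .lab_cross_day(config, "LAB/GLU")),
    hyponatremia = task_rate("LAB/NA", .lab_cross_day(config, "LAB/NA")),
    hyperkalemia = task_rate("LAB/K", .lab_cross_day(config, "LAB/K")),
    thrombocytopenia = task_rate("LAB/PLT", .lab_cross_day(config, "LAB/PLT")),
    anemia = task_rate("LAB/HGB", .lab_cross_day(config, "LAB/HGB")))
}

# ---- generation -------------------------------------------------------------

.sample_codes_by_state <- function(n_by_state, em) {
  # n_by_state: integer vector per state; returns character vector pooled
  out <- vector("list", length(n_by_state))
  for (s in seq_along(n_by_state)) {
    if (n_by_state[s] > 0) {
      out[[s]] <- sample(colnames(em), n_by_state[s], replace = TRUE,
                         prob = em[s, ])
    }
  }
  out
}

# simulate one admission block for a cohort of patients starting in states
# `st`; returns list(event rows, admission rows, last_state, died, los_days)
.sim_admissions <- function(config, site_id, pid, admit_day, st, em) {
  k <- config$n_states
  lab <- config$labs
  n <- length(pid)
  hd <- config$death_hazard; hc <- config$discharge_hazard
  Tm <- config$transition
  ev <- list(); ei <- 1L
  active <- rep(TRUE, n)
  died <- rep(FALSE, n)
  end_day <- rep(config$max_los_days, n)
  last_state <- st
  for (d in 0:config$max_los_days) {
    idx <- which(active)
    if (!length(idx)) break
    frac <- if (d == 0) config$day0_fraction else 1
    # non-lab coded events
    lam <- config$event_rate[st[idx]] * frac
    cnt <- rpois(length(idx), lam)
    if (sum(cnt) > 0) {
      who <- rep(idx, cnt)
      by_state <- tabulate(st[who], nbins = k)
      codes <- .sample_codes_by_state(by_state, em)
      ord <- order(st[who], method = "radix")
      code_vec <- character(length(who))
      code_vec[ord] <- unlist(codes)
      lo <- if (d == 0) 721 else 1
      hi <- if (d == 0) 1439 else 1379
      tm <- (admit_day[who] + d) * 1440 + floor(runif(length(who), lo, hi))
      ev[[ei]] <- data.frame(patient_id = pid[who], time = tm,
                             code = code_vec, value = NA_real_)
      ei <- ei + 1L
    }
    # lab events
    for (li in seq_along(lab$codes)) {
      lcnt <- rpois(length(idx), lab$lambda[li, st[idx]] * frac)
      if (sum(lcnt) > 0) {
        who <- rep(idx, lcnt)
        vals <- round(rnorm(length(who), lab$mu[li, st[who]], lab$sd[li]), 2)
        lo <- if (d == 0) 721 else 1
        hi <- if (d == 0) 1439 else 1379
        tm <- (admit_day[who] + d) * 1440 + floor(runif(length(who), lo, hi))
        ev[[ei]] <- data.frame(patient_id = pid[who], time = tm,
                               code = lab$codes[li], value = vals)
        ei <- ei + 1L
      }
    }
    # day-end hazards then transition
    u_death <- runif(length(idx)) < hd[st[idx]]
    u_disc <- runif(length(idx)) < hc[st[idx]]
    ends <- u_death | u_disc
    died[idx[u_death]] <- TRUE
    end_day[idx[ends]] <- d
    last_state[idx] <- st[idx]
    active[idx[ends]] <- FALSE
    stay <- idx[!ends]
    if (length(stay)) {
      st[stay] <- vapply(st[stay], function(s)
        sample.int(k, 1L, prob = Tm[s, ]), integer(1))
    }
  }
  end_time <- (admit_day + end_day) * 1440 + 1380   # 23:00 of final day
  adm <- data.frame(patient_id = pid,
                    admit_time = admit_day * 1440 + 720,
                    discharge_time = end_time,
                    death_time = ifelse(died, end_time, NA_real_))
  list(events = if (length(ev)) do.call(rbind, ev) else NULL,
       admissions = adm, last_state = last_state, died = died,
       los_days = end_day)
}

#' Generate one site's synthetic population
#'
#' Simulates `n_patients` timelines for the given site profile: a
#' pre-admission outpatient history emitted from the patient's initial
#' latent state, at least one hospital admission evolving under the latent
#' Markov model, and a possible 30-day readmission conditioned on the last
#' in-hospital state. Output is an OMOP-lite [TimelineSet-class]; identical
#' seeds give byte-identical populations.
#'
#' @param config a `synth_config` from [synthConfig()].
#' @param site_id "A" or "B".
#' @param seed RNG seed (default `config$seed`, offset per site).
#' @return a [TimelineSet-class].
#' @export
generateSitePopulation <- function(config, site_id, seed = NULL) {
  validateSynthConfig(config)
  sp <- config$sites[[site_id]]
  if (is.null(sp)) stop("unknown site: ", site_id)
  if (is.null(seed)) seed <- config$seed + match(site_id, names(config$sites))
  .run_seeded(seed, {
    n <- sp$n_patients
    k <- config$n_states
    em <- .emission_matrix(config, site_id)
    pid <- sprintf("%s-%05d", site_id, seq_len(n))
    sex <- sample(c("F", "M"), n, replace = TRUE)
    admit_day <- sample(18000:19400, n, replace = TRUE)  # 2019-2023
    age_days <- floor(runif(n, sp$age_days_range[1], sp$age_days_range[2]))
    birth_day <- admit_day - age_days
    s0 <- sample.int(k, n, replace = TRUE, prob = sp$initial_dist)

    # pre-admission outpatient history from the chronic (initial) state
    npre <- rpois(n, config$pre_events_mean)
    who <- rep(seq_len(n), npre)
    pre <- NULL
    if (length(who)) {
      by_state <- tabulate(s0[who], nbins = k)
      codes <- .sample_codes_by_state(by_state, em)
      ord <- order(s0[who], method = "radix")
      code_vec <- character(length(who))
      code_vec[ord] <- unlist(codes)
      back <- floor(runif(length(who), 1, config$pre_window_days * 1440))
      pre <- data.frame(patient_id = pid[who],
                        time = admit_day[who] * 1440 + 720 - back,
                        code = code_vec, value = NA_real_)
    }

    adm1 <- .sim_admissions(config, site_id, pid, admit_day, s0, em)

    # 30-day readmission for patients discharged alive
    alive <- which(!adm1$died)
    p_re <- config$readmit_prob[adm1$last_state[alive]]
    re <- alive[runif(length(alive)) < p_re]
    adm2 <- NULL
    if (length(re)) {
      gap <- sample(config$readmit_gap_days[1]:config$readmit_gap_days[2],
                    length(re), replace = TRUE)
      day2 <- admit_day[re] + adm1$los_days[re] + gap
      s0b <- sample.int(k, length(re), replace = TRUE, prob = sp$initial_dist)
      adm2 <- .sim_admissions(config, site_id, pid[re], day2, s0b, em)
    }

    persons <- data.frame(patient_id = pid, birth_date = birth_day * 1440,
                          sex = sex, site = site_id)
    ev <- rbind(pre, adm1$events, if (!is.null(adm2)) adm2$events)
    adms <- rbind(adm1$admissions, if (!is.null(adm2)) adm2$admissions)
    timelineSet(persons, ev, adms)
  })
}

#' Generate the default two-site study population
#'
#' Convenience wrapper generating both sites of a config and concatenating
#' them into one [TimelineSet-class].
#'
#' @param config a `synth_config`.
#' @param seed base seed (default `config$seed`).
#' @return a [TimelineSet-class] with both sites.
#' @export
generateStudyData <- function(config, seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  parts <- lapply(names(config$sites), function(sn)
    generateSitePopulation(config, sn, seed + match(sn, names(config$sites))))
  timelineSet(
    do.call(rbind, lapply(parts, persons)),
    do.call(rbind, lapply(parts, events)),
    do.call(rbind, lapply(parts, admissions)))
}

#' Summarize a synthetic or real corpus
#'
#' Per-site code frequency marginals, events per patient, and (when a seed
#' is supplied) the empirical per-task outcome prevalences of the inpatient
#' cohort built with the standard eligibility rules.
#'
#' @param timelines a [TimelineSet-class].
#' @param seed seed for the one-admission-per-patient cohort sampling; set
#'   to NULL to skip the prevalence table.
#' @return list with `marginals` (per site, named vectors),
#'   `events_per_patient` (per site), and `prevalence` (data.frame site x
#'   task, NULL when `seed` is NULL).
#' @export
summarizeCorpus <- function(timelines, seed = 1L) {
  stopifnot(is(timelines, "TimelineSet"))
  per <- persons(timelines)
  if (!nrow(per)) stop("empty corpus")
  ev <- events(timelines)
  sites <- sort(unique(per$site))
  marg <- lapply(sites, function(sn) {
    ids <- per$patient_id[per$site == sn]
    tab <- table(ev$code[ev$patient_id %in% ids])
    p <- as.numeric(tab) / sum(tab)
    setNames(p, names(tab))
  })
  names(marg) <- sites
  epp <- vapply(sites, function(sn) {
    ids <- per$patient_id[per$site == sn]
    sum(ev$patient_id %in% ids) / length(ids)
  }, numeric(1))
  prev <- NULL
  if (!is.null(seed)) {
    prev_rows <- list()
    for (sn in sites) {
      ids <- per$patient_id[per$site == sn]
      sub <- subsetPatients(timelines, ids)
      min_age <- if (sn == "B") 18 * 365 else 28
      coh <- buildInpatientCohort(sub, minAgeDays = min_age, seed = seed)
      for (tk in taskNames()) {
        ex <- labelTask(coh, taskSpec(tk), sub)
        prev_rows[[paste(sn, tk)]] <- data.frame(
          site = sn, task = tk, n = nrow(ex),
          prevalence = if (nrow(ex)) mean(ex$label) else NA_real_)
      }
    }
    prev <- do.call(rbind, prev_rows)
    rownames(prev) <- NULL
  }
  list(marginals = marg, events_per_patient = epp, prevalence = prev)
}

#' Subset a TimelineSet to given patients
#'
#' @param timelines a [TimelineSet-class].
#' @param patientIds character vector of patient ids to keep.
#' @return a [TimelineSet-class].
#' @export
subsetPatients <- function(timelines, patientIds) {
  per <- persons(timelines)
  ev <- events(timelines)
  adm <- admissions(timelines)
  per <- per[per$patient_id %in% patientIds, , drop = FALSE]
  ev <- ev[ev$patient_id %in% patientIds, , drop = FALSE]
  adm <- adm[adm$patient_id %in% patientIds, , drop = FALSE]
  rownames(per) <- rownames(ev) <- rownames(adm) <- NULL
  new("TimelineSet", persons = per, events = ev, admissions = adm)
}
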