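# Synthetic ICU EHR generator with a known ground-truth decision process.
#
# A latent daily severity in [0,1] follows a mean-reverting random walk.
# Each ICU day the (stochastic, severity-monotone) behavior policy chooses
# one of 5 corticosteroid dose actions. The stay terminates each day with a
# geometric discharge hazard; at termination the patient dies with a logistic
# probability in current severity and current action, else leaves alive.
# Treatment also shifts next-day severity. A discrete-severity variant of the
# same process is exactly enumerable, giving a dynamic-programming oracle for
# policy values.

#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic ICU cohort
#' generator. Defaults define the package's reference scenario: moderate
#' corticosteroid doses lower the death odds at high severity and raise them
#' at low severity, so a non-trivial severity-dependent optimal policy
#' exists; clinicians prescribe more steroids to sicker patients.
#'
#' @param n_admissions number of ICU admissions to simulate
#' @param seed RNG seed; identical configs give byte-identical outputs
#' @param mean_los_days mean stay length (geometric discharge hazard
#'   `1/mean_los_days` applied after each completed day)
#' @param max_los_days hard cap on stay length in days
#' @param severity list: `kappa` (mean-reversion rate), `mu` (attractor),
#'   `sigma` (daily Gaussian innovation), `init_shape1`/`init_shape2`
#'   (Beta shape of the initial septic severity, rescaled to
#'   `[init_floor, 1]`), `init_floor`
#' @param behavior list of `intercepts` and `slopes` (length 5): the
#'   behavior policy is `softmax(intercepts + slopes * severity)`, with
#'   slopes increasing in dose so sicker patients receive more steroids
#' @param outcome list: `intercept`, `severity_slope`, `tx_effects`
#'   (length-5 per-action log-odds shift, scaled by `severity - pivot`),
#'   `tx_base` (length-5 severity-independent per-action toxicity, log-odds),
#'   `pivot` — the death model at stay termination
#' @param tx_drift length-5 per-action coefficient moving next-day severity
#'   by `-tx_drift[action] * (severity - pivot)`
#' @param septic_fraction fraction of admissions with suspected infection and
#'   sepsis-range severity
#' @param late_onset_fraction fraction of septic admissions that start mild
#'   and deteriorate (sepsis onset after admission)
#' @param minor_fraction fraction aged under 18 (exclusion-rule fodder)
#' @param short_stay_fraction fraction staying under 24 h (exclusion fodder)
#' @param sampling_rates named events/day rates per variable class
#' @param missingness named per-class probability that a sampled value is lost
#' @param n_severity_levels grid size of the discrete-severity variant
#' @return an object of class `sim_config`
#' @export
sim_config <- function(n_admissions = 500,
                       seed = 1L,
                       mean_los_days = 8,
                       max_los_days = 60,
                       severity = list(),
                       behavior = list(),
                       outcome = list(),
                       tx_drift = c(0, 0.04, 0.08, 0.06, 0.02),
                       septic_fraction = 0.85,
                       late_onset_fraction = 0.10,
                       minor_fraction = 0.02,
                       short_stay_fraction = 0.04,
                       sampling_rates = c(vital = 6, lab = 1.3, drug_rate = 3),
                       missingness = c(vital = 0.05, lab = 0.12),
                       n_severity_levels = 21L) {
  severity <- utils::modifyList(list(kappa = 0.15, mu = 0.35, sigma = 0.07,
                                     init_shape1 = 2, init_shape2 = 3,
                                     init_floor = 0.22), severity)
  behavior <- utils::modifyList(list(intercepts = c(1.2, 0.2, -0.6, -1.4, -2.2),
                                     slopes = c(0, 1.5, 2.5, 3.0, 3.5)), behavior)
  outcome <- utils::modifyList(list(intercept = -3.0, severity_slope = 4.5,
                                    tx_effects = c(0, -1.5, -3.0, -2.0, 1.0),
                                    tx_base = c(0, 0.2, 0.3, 0.4, 0.8),
                                    pivot = 0.45), outcome)
  cfg <- list(n_admissions = as.integer(n_admissions), seed = as.integer(seed),
              mean_los_days = mean_los_days, max_los_days = as.integer(max_los_days),
              severity = severity, behavior = behavior, outcome = outcome,
              tx_drift = tx_drift, septic_fraction = septic_fraction,
              late_onset_fraction = late_onset_fraction,
              minor_fraction = minor_fraction,
              short_stay_fraction = short_stay_fraction,
              sampling_rates = sampling_rates, missingness = missingness,
              n_severity_levels = as.integer(n_severity_levels))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (is.na(cfg$n_admissions) || cfg$n_admissions < 0)
    stopf("n_admissions must be a non-negative integer")
  if (cfg$mean_los_days <= 1) stopf("mean_los_days must exceed 1 day")
  if (any(cfg$sampling_rates < 0) || any(cfg$missingness < 0))
    stopf("sampling and missingness rates must be non-negative")
  if (any(cfg$missingness > 1)) stopf("missingness rates must be probabilities")
  for (f in c("intercepts", "slopes"))
    if (length(cfg$behavior[[f]]) != 5L || any(!is.finite(cfg$behavior[[f]])))
      stopf("behavior$%s must be 5 finite coefficients", f)
  if (length(cfg$outcome$tx_effects) != 5L || any(!is.finite(cfg$outcome$tx_effects)))
    stopf("outcome$tx_effects must be 5 finite coefficients")
  if (length(cfg$tx_drift) != 5L) stopf("tx_drift must have 5 entries")
  with(cfg$severity, {
    if (sigma < 0 || kappa < 0 || kappa > 1 || init_shape1 <= 0 || init_shape2 <= 0)
      stopf("invalid severity process parameters")
  })
  frac <- c(cfg$septic_fraction, cfg$late_onset_fraction, cfg$minor_fraction,
            cfg$short_stay_fraction)
  if (any(frac < 0 | frac > 1)) stopf("fractions must lie in [0, 1]")
  invisible(cfg)
}

# ---- Ground-truth dynamics -------------------------------------------------

#' Behavior-policy action probabilities
#'
#' The severity-monotone softmax policy used by the simulated clinicians.
#'
#' @param severity numeric vector in `[0, 1]`
#' @param config a [sim_config()]
#' @return matrix `length(severity) x 5` of action probabilities (actions 0-4)
#' @export
behavior_action_probs <- function(severity, config) {
  logits <- outer(severity, config$behavior$slopes) +
    matrix(config$behavior$intercepts, length(severity), 5L, byrow = TRUE)
  p <- softmax_rows(logits)
  colnames(p) <- paste0("a", 0:4)
  p
}

# P(death | stay terminates now, severity, action index 0-4); the treatment
# enters as a severity-independent toxicity plus a severity-interaction term
# (beneficial above the pivot, harmful below it).
death_prob <- function(severity, action0, config) {
  oc <- config$outcome
  tx_base <- oc$tx_base %||% rep(0, 5)
  stats::plogis(oc$intercept + oc$severity_slope * severity +
                tx_base[action0 + 1L] +
                oc$tx_effects[action0 + 1L] * (severity - oc$pivot))
}

# mean of next-day severity before clipping to [0, 1]
next_severity_mean <- function(severity, action0, config) {
  sv <- config$severity
  severity + sv$kappa * (sv$mu - severity) -
    config$tx_drift[action0 + 1L] * (severity - config$outcome$pivot)
}

init_severity_quantile <- function(p, config) {
  sv <- config$severity
  sv$init_floor + (1 - sv$init_floor) * stats::qbeta(p, sv$init_shape1, sv$init_shape2)
}

# ---- Discrete-severity variant (the enumerable MDP) ------------------------

#' Discrete-severity Markov decision process
#'
#' Discretizes the generator's severity process onto a uniform grid, giving a
#' finite MDP whose exact policy values can be computed by dynamic
#' programming. Used as the oracle for the off-policy evaluation module and
#' for policy-recovery experiments.
#'
#' @param config a [sim_config()]
#' @param gamma discount factor for the value computation
#' @return object of class `severity_mdp`: grid `s`, per-action transition
#'   matrices `P`, death matrix `p_die` (levels x actions), discharge hazard
#'   `p_dis`, initial distribution `init`
#' @export
severity_mdp <- function(config, gamma = 1) {
  K <- config$n_severity_levels
  s <- seq(0, 1, length.out = K)
  half <- 1 / (2 * (K - 1))
  edges <- c(-Inf, s[-K] + half, Inf)
  sigma <- config$severity$sigma
  P <- lapply(0:4, function(a) {
    m <- next_severity_mean(s, a, config)
    pr <- vapply(seq_len(K), function(j)
      stats::pnorm(edges[j + 1], m, sigma) - stats::pnorm(edges[j], m, sigma),
      numeric(K))
    pr / rowSums(pr)
  })
  p_die <- vapply(0:4, function(a) death_prob(s, a, config), numeric(K))
  # initial distribution: mass of the rescaled Beta in each grid cell
  lo <- clip01((edges[1:K]     - config$severity$init_floor) / (1 - config$severity$init_floor))
  hi <- clip01((edges[2:(K+1)] - config$severity$init_floor) / (1 - config$severity$init_floor))
  init <- stats::pbeta(hi, config$severity$init_shape1, config$severity$init_shape2) -
          stats::pbeta(lo, config$severity$init_shape1, config$severity$init_shape2)
  init <- init / sum(init)
  structure(list(s = s, P = P, p_die = p_die, p_dis = 1 / config$mean_los_days,
                 init = init, gamma = gamma, max_days = config$max_los_days,
                 config = config),
            class = "severity_mdp")
}

# Coerce a policy argument (function of severity, or K x 5 matrix) to a
# row-stochastic K x 5 matrix over the MDP's severity grid.
policy_matrix <- function(policy, mdp) {
  pol <- if (is.function(policy)) {
    out <- policy(mdp$s)
    if (is.null(dim(out))) out <- do.call(rbind, lapply(mdp$s, policy))
    out
  } else policy
  pol <- as.matrix(pol)
  if (!all(dim(pol) == c(length(mdp$s), 5L)))
    stopf("policy must map the %d severity levels to 5 action probabilities",
          length(mdp$s))
  if (any(!is.finite(pol)) || any(pol < 0))
    stopf("policy probabilities must be finite and non-negative")
  if (any(abs(rowSums(pol) - 1) > 1e-8))
    stopf("policy rows must sum to 1")
  pol
}

#' Exact expected return of a policy (dynamic-programming oracle)
#'
#' Computes, with no sampling, the expected discounted terminal reward
#' (+1 alive discharge, -1 ICU death) of a stationary policy on the
#' discrete-severity MDP, by solving the linear Bellman system.
#'
#' @param x a [sim_config()] or a [severity_mdp()]
#' @param policy function mapping severity to 5 action probabilities, or a
#'   `levels x 5` matrix aligned to the MDP grid
#' @param gamma discount (used when `x` is a config)
#' @return scalar expected return under the initial severity distribution
#' @export
true_policy_value <- function(x, policy, gamma = 1) {
  mdp <- if (inherits(x, "sim_config")) severity_mdp(x, gamma) else x
  pol <- policy_matrix(policy, mdp)
  K <- length(mdp$s)
  # E[immediate terminal reward | s] and policy-averaged transition kernel
  r_term <- rowSums(pol * (1 - 2 * mdp$p_die)) * mdp$p_dis
  Pbar <- matrix(0, K, K)
  for (a in 1:5) Pbar <- Pbar + pol[, a] * mdp$P[[a]]
  V <- solve(diag(K) - mdp$gamma * (1 - mdp$p_dis) * Pbar, r_term)
  drop(mdp$init %*% V)
}

#' Simulate stays from the discrete-severity MDP
#'
#' Vectorized forward simulation of `n` ICU stays under a stationary policy,
#' recording per-day severity level, action, and the probability the
#' simulating policy assigned to the chosen action (needed downstream for
#' importance weighting).
#'
#' @param x a [sim_config()] or [severity_mdp()]
#' @param policy policy as in [true_policy_value()]
#' @param n number of stays
#' @param seed RNG seed
#' @return `data.table` with columns `stay_id`, `day`, `level`, `severity`,
#'   `action`, `p_action`, `terminal`, `reward`, `died`
#' @export
simulate_severity_stays <- function(x, policy, n, seed = 1L) {
  mdp <- if (inherits(x, "sim_config")) severity_mdp(x) else x
  pol <- policy_matrix(policy, mdp)
  K <- length(mdp$s)
  cumP <- lapply(mdp$P, function(p) t(apply(p, 1L, cumsum)))
  with_seed(seed, {
    level <- sample_rows(matrix(mdp$init, 1, K)[rep(1, n), , drop = FALSE])
    active <- seq_len(n)
    rows <- vector("list", mdp$max_days)
    day <- 0L
    while (length(active) && day < mdp$max_days) {
      m <- length(active)
      a <- sample_rows(pol[level, , drop = FALSE])          # 1..5
      p_a <- pol[cbind(level, a)]
      term <- stats::runif(m) < mdp$p_dis | day == mdp$max_days - 1L
      died <- rep(FALSE, m)
      died[term] <- stats::runif(sum(term)) <
        mdp$p_die[cbind(level[term], a[term])]
      rows[[day + 1L]] <- data.table::data.table(
        stay_id = active, day = day, level = level,
        severity = mdp$s[level], action = a - 1L, p_action = p_a,
        terminal = term,
        reward = ifelse(term, ifelse(died, -1, 1), 0),
        died = died)
      keep <- !term
      if (any(keep)) {
        lv <- level[keep]; ak <- a[keep]
        u <- stats::runif(sum(keep))
        nl <- integer(sum(keep))
        for (act in unique(ak)) {
          idx <- ak == act
          cp <- cumP[[act]][lv[idx], , drop = FALSE]
          nl[idx] <- 1L + rowSums(u[idx] > cp[, -K, drop = FALSE])
        }
        level <- nl
        active <- active[keep]
      } else {
        active <- integer(0)
      }
      day <- day + 1L
    }
    out <- data.table::rbindlist(rows[!vapply(rows, is.null, logical(1))])
    data.table::setorder(out, stay_id, day)
    out[]
  })
}

#' Convert simulated stays to a trajectory set
#'
#' Packages the output of [simulate_severity_stays()] as a
#' [trajectory_set] whose single state feature is severity rescaled to
#' `[-1, 1]`, ready for actor-critic training and off-policy evaluation.
#'
#' @param sim output of [simulate_severity_stays()]
#' @param gamma discount used for returns
#' @param features `"severity"` (single rescaled severity feature, default)
#'   or `"onehot"` (one indicator per severity level — the tabular
#'   featurization for small enumerable MDPs)
#' @param n_levels number of levels for the one-hot encoding
#' @return a `trajectory_set` (see [build_trajectories()])
#' @export
severity_trajectories <- function(sim, gamma = 1,
                                  features = c("severity", "onehot"),
                                  n_levels = max(sim$level)) {
  features <- match.arg(features)
  X <- if (features == "severity") {
    matrix(2 * sim$severity - 1, ncol = 1, dimnames = list(NULL, "severity"))
  } else {
    M <- matrix(-1, nrow(sim), n_levels,
                dimnames = list(NULL, paste0("level", seq_len(n_levels))))
    M[cbind(seq_len(nrow(sim)), sim$level)] <- 1
    M
  }
  # zero-padded ids keep the character ordering of the trajectory set
  # identical to the numeric row order of `sim`
  new_trajectory_set(X = X, admission_id = sprintf("s%08d", sim$stay_id),
                     day_index = sim$day, action = sim$action,
                     reward = sim$reward, terminal = sim$terminal,
                     gamma = gamma, behavior_prob = sim$p_action)
}

# ---- Continuous event-level generator --------------------------------------

lab_variables <- function() {
  c("lactate", "creatinine", "bilirubin", "platelets", "glucose", "sodium",
    "wbc", "pf_ratio", "gcs", "urine_output", "csf_protein")
}

# Noiseless physiology: expected measurement value at a given severity.
phys_mean <- function(var, s) {
  switch(var,
    heart_rate   = 72 + 45 * s,
    map          = 86 - 28 * s,
    lactate      = 0.8 + 4.5 * s,
    creatinine   = 0.8 + 2.8 * s,
    bilirubin    = 0.6 + 3.5 * s,
    platelets    = 260 - 210 * s,
    glucose      = 6 + 4 * s,
    sodium       = 140 + 4 * (s - 0.4),
    wbc          = 9 + 9 * s,
    pf_ratio     = 460 - 300 * s,
    gcs          = 15 - 7 * s,
    urine_output = 2200 - 2600 * s,
    csf_protein  = 0.4 + 0.6 * s,
    stopf("unknown variable %s", var))
}

phys_noise_sd <- function(var) {
  c(heart_rate = 6, map = 6, lactate = 0.5, creatinine = 0.25, bilirubin = 0.3,
    platelets = 25, glucose = 1, sodium = 2, wbc = 2, pf_ratio = 30,
    gcs = 0.8, urine_output = 200, csf_protein = 0.15)[[var]]
}

phys_floor <- function(var) {
  c(heart_rate = 20, map = 20, lactate = 0.2, creatinine = 0.2, bilirubin = 0.05,
    platelets = 5, glucose = 2, sodium = 110, wbc = 0.5, pf_ratio = 40,
    gcs = 3, urine_output = 0, csf_protein = 0.05)[[var]]
}

# Deterministic SOFA total implied by the noiseless physiology at severity s;
# used to derive the generator's ground-truth sepsis label.
noiseless_sofa <- function(s) {
  vent <- s > 0.6
  ne <- ifelse(s > 0.55, 0.04 + 0.25 * (s - 0.55), NA_real_)
  sofa_respiration(phys_mean("pf_ratio", s), vent) +
    sofa_coagulation(phys_mean("platelets", s)) +
    sofa_liver(phys_mean("bilirubin", s)) +
    sofa_cardio(phys_mean("map", s), norepinephrine = ne) +
    sofa_cns(round(phys_mean("gcs", s))) +
    sofa_renal(phys_mean("creatinine", s), phys_mean("urine_output", s))
}

empty_admissions <- function() data.table::data.table(
  admission_id = character(), patient_id = character(), age_years = integer(),
  sex = character(), admitted_at = as.POSIXct(character(), tz = "UTC"),
  discharged_at = as.POSIXct(character(), tz = "UTC"), died_in_icu = logical())

empty_events <- function() data.table::data.table(
  admission_id = character(), variable_name = character(),
  timestamp = as.POSIXct(character(), tz = "UTC"),
  numeric_value = numeric(), variable_class = character())

empty_ground_truth <- function() data.table::data.table(
  admission_id = character(), day_index = integer(), severity = numeric(),
  true_action = integer(), hydro_dose_mg = numeric(), true_septic = logical(),
  sepsis_onset_day = integer(), died_in_icu = logical())

#' Generate a synthetic ICU cohort
#'
#' Simulates admissions, an event table of irregularly sampled vitals,
#' laboratory values, drug administrations and culture samples, and a
#' ground-truth table exposing the latent per-day severity and the true
#' behavior-policy action — everything downstream modules need, with oracles.
#'
#' Severity drives the physiology (blood pressure falls, lactate and
#' creatinine rise with severity), vasopressor use, corticosteroid
#' prescription via the behavior policy, and death via the outcome model.
#' A configurable fraction of admissions receive antibiotic/culture pairs
#' (suspected infection); under-18 and sub-24 h admissions are included as
#' exclusion-rule fodder.
#'
#' @param config a [sim_config()]
#' @return list with `admissions`, `events`, `ground_truth` data.tables
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_admissions
  if (n == 0L) return(list(admissions = empty_admissions(),
                           events = empty_events(),
                           ground_truth = empty_ground_truth()))
  with_seed(config$seed, {
    adm <- make_admission_frame(config, n)
    days <- simulate_day_table(config, adm)
    days[, hydro_dose_mg := draw_steroid_dose(action)]
    # terminal disposition back onto admissions
    term <- days[, .(los_days = .N, died_in_icu = any(died)), by = admission_idx]
    adm$died_in_icu <- term$died_in_icu[match(seq_len(n), term$admission_idx)]
    los_hours <- ifelse(adm$short_stay, adm$short_hours,
                        term$los_days[match(seq_len(n), term$admission_idx)] * 24)
    adm$discharged_at <- adm$admitted_at + round(los_hours * 3600)
    events <- build_event_table(config, adm, days)
    gt <- build_ground_truth(config, adm, days)
    admissions <- adm[, .(admission_id, patient_id, age_years, sex,
                          admitted_at, discharged_at, died_in_icu)]
    list(admissions = admissions, events = events, ground_truth = gt)
  })
}

make_admission_frame <- function(config, n) {
  n_pat <- max(1L, floor(n * 0.965))
  adm <- data.table::data.table(
    admission_idx = seq_len(n),
    admission_id = sprintf("a%06d", seq_len(n)),
    patient_id = sprintf("p%06d", sample.int(n_pat, n, replace = TRUE)),
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.576, 0.424)),
    admitted_at = as.POSIXct("2014-01-01 00:00:00", tz = "UTC") +
      round(stats::runif(n, 0, 3 * 365 * 86400)))
  adm$age_years <- ifelse(stats::runif(n) < config$minor_fraction,
                          sample(14:17, n, replace = TRUE),
                          sample(18:95, n, replace = TRUE,
                                 prob = stats::dnorm(18:95, 66, 16)))
  adm$septic <- stats::runif(n) < config$septic_fraction
  adm$late_onset <- adm$septic & stats::runif(n) < config$late_onset_fraction
  adm$short_stay <- stats::runif(n) < config$short_stay_fraction
  adm$short_hours <- stats::runif(n, 6, 23)
  adm$init_severity <- ifelse(
    adm$septic & !adm$late_onset,
    init_severity_quantile(stats::runif(n), config),
    ifelse(adm$late_onset, stats::runif(n, 0.05, 0.12),
           stats::rbeta(n, 1.2, 8)))
  adm
}

# Latent severity / action / termination paths, one row per admission-day.
simulate_day_table <- function(config, adm) {
  n <- nrow(adm)
  p_dis <- 1 / config$mean_los_days
  sv <- config$severity
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- adm$init_severity[i]
    # late-onset admissions deteriorate: severity attracted upward
    mu_i <- if (adm$late_onset[i]) 0.55 else sv$mu
    day <- 0L
    ss <- numeric(); aa <- integer(); dd <- logical(); tt <- logical()
    repeat {
      pr <- behavior_action_probs(s, config)
      a <- sample_rows(pr) - 1L
      short <- adm$short_stay[i]
      term <- short || day >= config$max_los_days - 1L ||
        stats::runif(1) < p_dis
      died <- term && stats::runif(1) < death_prob(s, a, config)
      ss <- c(ss, s); aa <- c(aa, a); tt <- c(tt, term); dd <- c(dd, died)
      if (term) break
      drift <- sv$kappa * (mu_i - s) -
        config$tx_drift[a + 1L] * (s - config$outcome$pivot)
      s <- clip01(s + drift + stats::rnorm(1, 0, sv$sigma))
      day <- day + 1L
    }
    out[[i]] <- data.table::data.table(admission_idx = i,
                                       day = seq_along(ss) - 1L,
                                       severity = ss, action = aa,
                                       terminal = tt, died = dd)
  }
  data.table::rbindlist(out)
}

# Corticosteroid daily dose: bin midpoint plus jitter kept clear of the bin
# boundaries so dose discretization recovers the true action exactly.
draw_steroid_dose <- function(action0) {
  n <- length(action0)
  mid <- c(0, 50, 150, 250, 350)[action0 + 1L]
  jit <- stats::runif(n, -35, 35)
  jit[action0 == 4L] <- stats::runif(sum(action0 == 4L), -40, 200)
  ifelse(action0 == 0L, 0, mid + jit)
}

build_event_table <- function(config, adm, days) {
  dt <- data.table::copy(days)
  dt[, admission_id := adm$admission_id[admission_idx]]
  dt[, t0 := adm$admitted_at[admission_idx] + day * 86400]
  # the last (partial) day of a short stay spans only its few hours
  dt[, window_h := ifelse(adm$short_stay[admission_idx],
                          adm$short_hours[admission_idx], 24)]
  ev <- list()
  rate_v <- config$sampling_rates[["vital"]]
  rate_l <- config$sampling_rates[["lab"]]
  miss_v <- config$missingness[["vital"]]
  miss_l <- config$missingness[["lab"]]
  emit <- function(rows, k, var, class, values_fn) {
    idx <- rep(seq_len(nrow(rows)), k)
    if (!length(idx)) return(NULL)
    s <- rows$severity[idx]
    val <- values_fn(var, s)
    data.table::data.table(
      admission_id = rows$admission_id[idx],
      variable_name = var,
      timestamp = rows$t0[idx] +
        round(stats::runif(length(idx), 0, rows$window_h[idx] * 3600 - 1)),
      numeric_value = val,
      variable_class = class)
  }
  noisy <- function(var, s) {
    v <- pmax(phys_floor(var),
              phys_mean(var, s) + stats::rnorm(length(s), 0, phys_noise_sd(var)))
    if (var == "gcs") v <- round(clip(v, 3, 15))
    v
  }
  for (var in c("heart_rate", "map")) {
    k <- stats::rbinom(nrow(dt), stats::rpois(nrow(dt), rate_v), 1 - miss_v)
    ev[[var]] <- emit(dt, k, var, "vital", noisy)
  }
  for (var in setdiff(lab_variables(), "csf_protein")) {
    k <- stats::rbinom(nrow(dt), stats::rpois(nrow(dt), rate_l), 1 - miss_l)
    ev[[var]] <- emit(dt, k, var, "lab", noisy)
  }
  # rare laboratory value (exercises the coverage filter)
  k <- stats::rpois(nrow(dt), 0.012)
  ev[["csf_protein"]] <- emit(dt, k, "csf_protein", "lab", noisy)
  # ventilation flag on severely hypoxemic days
  vent <- dt[severity > 0.6]
  if (nrow(vent)) ev[["ventilated"]] <-
    emit(vent, 1L, "ventilated", "ventilation", function(var, s) rep(1, length(s)))
  # vasopressor infusion rate (ug/kg/min) on shocked days
  pressor <- dt[severity > 0.55]
  if (nrow(pressor)) {
    k <- stats::rpois(nrow(pressor), config$sampling_rates[["drug_rate"]])
    ev[["norepinephrine"]] <- emit(pressor, k, "norepinephrine", "drug_rate",
      function(var, s) pmax(0.01, 0.04 + 0.25 * (s - 0.55) +
                                  stats::rnorm(length(s), 0, 0.02)))
  }
  # corticosteroid boluses; compound mix with exact hydrocortisone equivalence
  dosed <- dt[action > 0L]
  if (nrow(dosed)) {
    dosed <- data.table::copy(dosed)
    dosed[, hydro := hydro_dose_mg]
    compounds <- names(steroid_potency())[c(1, 3, 5, 6)]
    pick <- sample(compounds, nrow(dosed), replace = TRUE,
                   prob = c(0.5, 0.25, 0.15, 0.10))
    pot <- steroid_potency()[pick]
    ev[["steroid"]] <- data.table::data.table(
      admission_id = dosed$admission_id,
      variable_name = pick,
      timestamp = dosed$t0 + round(stats::runif(nrow(dosed), 0,
                                                dosed$window_h * 3600 - 1)),
      numeric_value = dosed$hydro / pot,
      variable_class = "drug_bolus")
  }
  # suspected infection: culture + antibiotic pair for septic admissions;
  # some non-septic admissions get antibiotics without a culture
  sep <- adm[adm$septic, ]
  if (nrow(sep)) {
    cul_t <- sep$admitted_at + round(stats::runif(nrow(sep), 0, 12 * 3600))
    abx_t <- cul_t + round(stats::runif(nrow(sep), -6, 48) * 3600)
    abx_t <- pmax(abx_t, sep$admitted_at)
    ev[["culture"]] <- data.table::data.table(
      admission_id = sep$admission_id, variable_name = "blood_culture",
      timestamp = cul_t, numeric_value = 1, variable_class = "culture")
    ev[["abx"]] <- data.table::data.table(
      admission_id = sep$admission_id,
      variable_name = sample(paste0(antibiotic_prefix(),
                                    c("ceftriaxone", "piperacillin", "meropenem")),
                             nrow(sep), replace = TRUE),
      timestamp = abx_t, numeric_value = 2000, variable_class = "drug_bolus")
  }
  nonsep <- adm[!adm$septic, ]
  nonsep <- nonsep[stats::runif(nrow(nonsep)) < 0.3, ]
  if (nrow(nonsep)) ev[["abx_only"]] <- data.table::data.table(
    admission_id = nonsep$admission_id,
    variable_name = paste0(antibiotic_prefix(), "cefazolin"),
    timestamp = nonsep$admitted_at + round(stats::runif(nrow(nonsep), 0, 20 * 3600)),
    numeric_value = 2000, variable_class = "drug_bolus")
  events <- data.table::rbindlist(ev[!vapply(ev, is.null, logical(1))])
  # keep timestamps inside the owning admission interval
  dis <- adm$discharged_at[match(events$admission_id, adm$admission_id)]
  bgn <- adm$admitted_at[match(events$admission_id, adm$admission_id)]
  events[, timestamp := pmin(pmax(timestamp, bgn), dis - 1)]
  data.table::setorder(events, admission_id, timestamp, variable_name)
  events[]
}

build_ground_truth <- function(config, adm, days) {
  gt <- days[, .(admission_idx, day_index = day, severity, true_action = action,
                 hydro_dose_mg, died)]
  gt[, admission_id := adm$admission_id[admission_idx]]
  # ground-truth sepsis label: infection pair plus the SOFA rule applied to
  # the noiseless physiology along the latent path
  qual <- days[, {
    tot <- noiseless_sofa(severity)
    q0 <- tot[1] >= 2
    rise <- if (.N > 1) vapply(2:.N, function(d) tot[d] - min(tot[1:(d - 1)]) >= 2,
                               logical(1)) else logical(0)
    onset <- if (q0) 0L else if (any(rise)) which(rise)[1] else NA_integer_
    .(qualifies = q0 || any(rise), onset_day = onset)
  }, by = admission_idx]
  gt <- merge(gt, qual, by = "admission_idx")
  gt[, true_septic := adm$septic[admission_idx] & qualifies]
  gt[, sepsis_onset_day := data.table::fifelse(true_septic, onset_day, NA_integer_)]
  gt[, died_in_icu := adm$died_in_icu[admission_idx]]
  data.table::setorder(gt, admission_id, day_index)
  gt[, .(admission_id, day_index, severity, true_action, hydro_dose_mg,
         true_septic, sepsis_onset_day, died_in_icu)]
}

#' Write a synthetic cohort to delimited-text files
#'
#' Writes `admissions.csv`, `events.csv` and `ground_truth.csv` (RFC-4180
#' quoting, ISO-8601 UTC timestamps) to a directory.
#'
#' @param cohort result of [generate_cohort()]
#' @param dir output directory (created if absent)
#' @return invisibly, the paths written
#' @export
write_synthetic_ehr <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  a <- data.table::copy(cohort$admissions)
  a[, admitted_at := iso8601(admitted_at)]
  a[, discharged_at := iso8601(discharged_at)]
  e <- data.table::copy(cohort$events)
  e[, timestamp := iso8601(timestamp)]
  paths <- file.path(dir, c("admissions.csv", "events.csv", "ground_truth.csv"))
  data.table::fwrite(a, paths[1])
  data.table::fwrite(e, paths[2])
  data.table::fwrite(cohort$ground_truth, paths[3])
  invisible(paths)
}
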