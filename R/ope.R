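# High-confidence off-policy evaluation: behavior-policy estimation,
# trajectory-level truncated importance sampling, lower confidence bounds on
# the evaluation policy's expected return, and concordance-stratified
# outcome analysis.

#' Estimate the clinician behavior policy
#'
#' Wraps either a fitted behavior clone (probability forest) or empirical
#' per-state-cluster action frequencies as a behavior policy b(a|s), with a
#' probability floor applied and renormalized so no logged action ever has
#' zero probability under b.
#'
#' @param x a `behavior_clone` (see [fit_behavior_clone()]) or a
#'   `trajectory_set` (empirical frequencies over k-means state clusters)
#' @param p_min probability floor (must be below 0.2, else the floor would
#'   flatten the 5-way distribution)
#' @param n_clusters clusters for the empirical estimator
#' @param seed seed for the clustering
#' @return object of class `behavior_policy` with a `$predict(X)` method
#'   returning an `n x 5` probability matrix
#' @export
estimate_behavior_policy <- function(x, p_min = 0.01, n_clusters = 50L,
                                     seed = 1L) {
  if (p_min >= 0.2) stopf("p_min must be below 0.2 (5 actions must remain distinguishable)")
  if (p_min <= 0) stopf("p_min must be positive")
  floor_probs <- function(p) {
    p <- pmax(p, p_min)
    p / rowSums(p)
  }
  if (inherits(x, "behavior_clone")) {
    predict_fn <- function(X) floor_probs(predict_clone_probs(x, X))
    provenance <- "behavior_clone"
  } else if (inherits(x, "trajectory_set")) {
    n_distinct <- nrow(unique(x$X))
    km <- with_seed(seed, stats::kmeans(x$X,
                                        centers = min(n_clusters, n_distinct),
                                        nstart = 3, iter.max = 50))
    counts <- matrix(0, nrow(km$centers), 5L)
    for (a in 0:4) {
      t_a <- table(factor(km$cluster[x$action == a],
                          levels = seq_len(nrow(km$centers))))
      counts[, a + 1L] <- as.integer(t_a)
    }
    freq <- (counts + 0.5) / rowSums(counts + 0.5)
    centers <- km$centers
    predict_fn <- function(X) {
      X <- as.matrix(X)
      d2 <- outer(rowSums(X^2), rowSums(centers^2), "+") -
        2 * X %*% t(centers)
      floor_probs(freq[max.col(-d2, ties.method = "first"), , drop = FALSE])
    }
    provenance <- "empirical"
  } else stopf("x must be a behavior_clone or a trajectory_set")
  structure(list(predict = predict_fn, p_min = p_min, provenance = provenance),
            class = "behavior_policy")
}

#' Trajectory-level truncated importance weights
#'
#' `w(tau) = min(c, prod_t pi_e(a_t|s_t) / b(a_t|s_t))` over the logged
#' actions of each trajectory.
#'
#' @param traj a `trajectory_set`
#' @param pi_e_probs `n x 5` evaluation-policy probabilities per logged
#'   day-state (e.g. [policy_probs()])
#' @param b_probs `n x 5` behavior-policy probabilities, or a vector of the
#'   behavior probability of the logged action per day-state
#' @param c truncation level (default 100; `Inf` for untruncated)
#' @return numeric vector of per-trajectory weights
#' @export
importance_weights <- function(traj, pi_e_probs, b_probs, c = 100) {
  a1 <- traj$action + 1L
  pe <- as.matrix(pi_e_probs)[cbind(seq_along(a1), a1)]
  pb <- if (is.null(dim(b_probs))) as.numeric(b_probs)
        else as.matrix(b_probs)[cbind(seq_along(a1), a1)]
  if (any(pb <= 0))
    stopf("behavior policy assigns zero probability to a logged action; apply a probability floor")
  lw <- vapply(split(log(pe) - log(pb), traj$traj_id), sum, numeric(1))
  pmin(c, exp(unname(lw)))
}

#' High-confidence lower bound on the expected return
#'
#' Computes a `1 - delta` lower confidence bound on the mean of (importance-
#' weighted) returns. The default `concentration` method is the
#' empirical-Bernstein bound
#' `mean - sqrt(2 v log(2/delta) / n) - 7 R log(2/delta) / (3 (n - 1))`
#' with `v` the sample variance and `R` the empirical range (a degenerate
#' all-equal sample therefore returns that constant). `t_test` is the
#' one-sided Student bound `mean - t_{1-delta, n-1} s / sqrt(n)`;
#' `bootstrap_bca` a bias-corrected accelerated percentile bound.
#'
#' @param x weighted returns, one per trajectory (at least 30)
#' @param delta confidence level (default 0.05 for a 95% bound)
#' @param method one of `concentration`, `t_test`, `bootstrap_bca`
#' @param n_boot bootstrap replicates for `bootstrap_bca`
#' @return scalar lower bound
#' @export
hcope_lower_bound <- function(x, delta = 0.05,
                              method = c("concentration", "t_test",
                                         "bootstrap_bca"),
                              n_boot = 2000L) {
  method <- match.arg(method)
  n <- length(x)
  if (n < 30) stopf("at least 30 trajectories are required for the bound")
  m <- mean(x)
  switch(method,
    concentration = {
      v <- stats::var(x)
      R <- diff(range(x))
      lg <- log(2 / delta)
      m - sqrt(2 * v * lg / n) - 7 * R * lg / (3 * (n - 1))
    },
    t_test = m - stats::qt(1 - delta, n - 1) * stats::sd(x) / sqrt(n),
    bootstrap_bca = {
      if (stats::sd(x) == 0) return(m)
      means <- vapply(seq_len(n_boot), function(i)
        mean(x[sample.int(n, n, replace = TRUE)]), numeric(1))
      z0 <- stats::qnorm(mean(means < m))
      jack <- (sum(x) - x) / (n - 1)
      jm <- mean(jack)
      acc_num <- sum((jm - jack)^3)
      acc_den <- 6 * sum((jm - jack)^2)^1.5
      a <- if (acc_den == 0) 0 else acc_num / acc_den
      za <- stats::qnorm(delta)
      alpha <- stats::pnorm(z0 + (z0 + za) / (1 - a * (z0 + za)))
      unname(stats::quantile(means, alpha, type = 7))
    })
}

#' Normalized expected mortality of the evaluation policy
#'
#' With terminal rewards of +1 (alive discharge) and -1 (ICU death), the
#' expected mortality implied by a policy value J is `(1 - J) / 2`; the
#' normalized rate benchmarks it against the clinician estimate.
#'
#' @param j_eval evaluation-policy value estimate
#' @param j_behavior behavior-policy value estimate
#' @return `((1 - j_eval)/2) / ((1 - j_behavior)/2)`
#' @export
normalized_expected_mortality <- function(j_eval, j_behavior) {
  ((1 - j_eval) / 2) / ((1 - j_behavior) / 2)
}

#' Off-policy evaluation report
#'
#' Weighted importance-sampling point estimate, high-confidence lower bound,
#' behavior estimate and normalized expected mortality for an evaluation
#' policy against the logged data.
#'
#' @param traj a `trajectory_set` (typically the validation split)
#' @param pi_e_probs evaluation-policy probabilities on the logged day-states
#' @param b_probs behavior-policy probabilities (matrix or logged-action
#'   vector)
#' @param c truncation level
#' @param delta confidence level
#' @param method bound method, see [hcope_lower_bound()]
#' @return list of class `ope_report`
#' @export
ope_report <- function(traj, pi_e_probs, b_probs, c = 100, delta = 0.05,
                       method = "concentration") {
  w <- importance_weights(traj, pi_e_probs, b_probs, c = c)
  wr <- w * traj$returns
  j_b <- mean(traj$returns)
  j_e <- mean(wr)
  lb <- hcope_lower_bound(wr, delta = delta, method = method)
  structure(list(weights = w, point_estimate = j_e,
                 lower_bound_95 = lb, behavior_estimate = j_b,
                 normalized_expected_mortality =
                   normalized_expected_mortality(j_e, j_b),
                 exceeds_behavior = lb > j_b,
                 truncation = c, delta = delta, method = method,
                 n_trajectories = traj$n_traj),
            class = "ope_report")
}

#' Concordance-stratified outcome analysis
#'
#' Labels each day-state concordant iff the agent's recommendation equals the
#' logged clinician action, then compares day-level mortality (the fraction
#' of day-states belonging to admissions that died in the ICU) between
#' concordant and discordant day-states — overall, stratified by whether the
#' agent withheld (action 0) or prescribed (actions 1-4), and by septic-shock
#' status when episodes are supplied.
#'
#' @param model an `actor_critic`
#' @param traj a `trajectory_set` (test split)
#' @param episodes optional episode table with `septic_shock`
#' @return `data.table` with one row per stratum: day counts and mortality
#'   rates for concordant and discordant day-states (`NA` rates for empty
#'   strata, which are also flagged)
#' @export
concordance_outcomes <- function(model, traj, episodes = NULL) {
  rec <- recommend_action(model, traj$X)
  died_traj <- traj$returns[traj$traj_id] < 0
  dt <- data.table::data.table(admission_id = traj$admission_id,
                               concordant = rec == traj$action,
                               agent_withheld = rec == 0L,
                               died = died_traj)
  if (!is.null(episodes)) {
    ep <- data.table::as.data.table(episodes)
    dt[, septic_shock := ep$septic_shock[match(admission_id, ep$admission_id)]]
  }
  strata <- list(overall = rep(TRUE, nrow(dt)),
                 agent_withheld = dt$agent_withheld,
                 agent_prescribed = !dt$agent_withheld)
  if (!is.null(episodes)) {
    strata$septic_shock <- dt$septic_shock %in% TRUE
    strata$no_septic_shock <- dt$septic_shock %in% FALSE
  }
  rows <- lapply(names(strata), function(nm) {
    sel <- strata[[nm]]
    cc <- dt[sel & concordant]; dd <- dt[sel & !concordant]
    data.table::data.table(
      stratum = nm,
      concordant_days = nrow(cc), discordant_days = nrow(dd),
      concordant_mortality = if (nrow(cc)) mean(cc$died) else NA_real_,
      discordant_mortality = if (nrow(dd)) mean(dd$died) else NA_real_,
      empty_stratum = nrow(cc) == 0 || nrow(dd) == 0)
  })
  data.table::rbindlist(rows)
}

#' Per-day corticosteroid usage and dose curves
#'
#' For each day since sepsis onset, the percentage of still-present
#' admissions receiving any corticosteroid and the mean daily
#' hydrocortisone-equivalent dose, under the logged clinician actions and the
#' agent's recommendations. Doses use the action-bin midpoints (350 mg for
#' the open top bin) unless actual clinician doses are supplied.
#'
#' @param model an `actor_critic`
#' @param traj a `trajectory_set`
#' @param doses optional numeric vector of actual daily doses aligned to the
#'   trajectory rows (used for the clinician curve)
#' @return `data.table` keyed by `day_index` with usage percentages and mean
#'   doses for both policies
#' @export
policy_comparison_curves <- function(model, traj, doses = NULL) {
  rec <- recommend_action(model, traj$X)
  mid <- ACTION_BIN_MIDPOINTS
  dt <- data.table::data.table(
    day_index = traj$day_index,
    clin_any = traj$action > 0L,
    clin_dose = if (is.null(doses)) mid[traj$action + 1L] else doses,
    agent_any = rec > 0L,
    agent_dose = mid[rec + 1L])
  out <- dt[, .(n_present = .N,
                clinician_usage_pct = 100 * mean(clin_any),
                clinician_mean_dose = mean(clin_dose),
                agent_usage_pct = 100 * mean(agent_any),
                agent_mean_dose = mean(agent_dose)),
            by = day_index]
  data.table::setorder(out, day_index)
  out[]
}
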