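# Off-policy evaluation: behavior-policy floor, importance weights,
# lower-bound methods, concordance-stratified outcomes, usage curves.

test_that("the behavior-policy floor renormalizes and rejects degenerate floors", {
  clone_like <- structure(list(), class = "behavior_clone")
  expect_error(estimate_behavior_policy(clone_like, p_min = 0.25), "0.2")
  expect_error(estimate_behavior_policy(clone_like, p_min = 0), "positive")
  # empirical estimator on simulated data: floored probabilities stay a
  # distribution with the minimum respected
  cfg <- sim_config()
  sim <- simulate_severity_stays(severity_mdp(cfg),
                                 function(s) behavior_action_probs(s, cfg),
                                 400, seed = 6)
  tr <- severity_trajectories(sim)
  bp <- estimate_behavior_policy(tr, p_min = 0.01, n_clusters = 10)
  P <- bp$predict(tr$X)
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-10)
  expect_true(all(P >= 0.01 / (1 + 5 * 0.01)))
  expect_identical(bp$provenance, "empirical")
})

test_that("the empirical behavior estimate recovers the generator's marginal action mix", {
  cfg <- sim_config()
  sim <- simulate_severity_stays(severity_mdp(cfg),
                                 function(s) behavior_action_probs(s, cfg),
                                 1500, seed = 8)
  tr <- severity_trajectories(sim)
  bp <- estimate_behavior_policy(tr, p_min = 0.01, n_clusters = 25)
  marg_hat <- colMeans(bp$predict(tr$X))
  marg_logged <- as.numeric(table(factor(tr$action, levels = 0:4))) / length(tr$action)
  se <- sqrt(marg_logged * (1 - marg_logged) / length(tr$action))
  expect_true(all(abs(marg_hat - marg_logged) < 3 * se + 0.02))
})

unit_traj <- function(actions, pe, pb) {
  n <- length(actions)
  manual_trajectory_set(matrix(0, n, 1, dimnames = list(NULL, "s")),
                        sprintf("t%03d", seq_len(n)), rep(0L, n),
                        actions, rep(1, n), rep(TRUE, n), gamma = 1)
}

test_that("importance weights are products of probability ratios, truncated", {
  tr <- unit_traj(c(0L, 1L))
  pe <- rbind(c(0.5, 0.1, 0.2, 0.1, 0.1), c(0.2, 0.5, 0.1, 0.1, 0.1))
  pb <- rbind(c(0.25, 0.3, 0.15, 0.15, 0.15), c(0.2, 0.25, 0.15, 0.2, 0.2))
  w <- importance_weights(tr, pe, pb, c = 100)
  expect_equal(w, c(2, 2))
  # identical policies give weight 1 on every trajectory
  expect_equal(importance_weights(tr, pb, pb, c = 100), c(1, 1))
  # truncation caps the product
  pe_big <- rbind(c(1e6 * 0.25, 0, 0, 0, 0), c(0.2, 0.25, 0.15, 0.2, 0.2))
  pe_big <- pe_big / rowSums(pe_big)
  w_big <- importance_weights(tr, pe_big * 1e6, pb, c = 100)
  expect_equal(w_big[1], 100)
  # zero behavior probability on a logged action errors
  pb0 <- pb; pb0[1, 1] <- 0
  expect_error(importance_weights(tr, pe, pb0, c = 100), "zero probability")
})

test_that("multi-step weights multiply per-step ratios", {
  X <- matrix(0, 3, 1, dimnames = list(NULL, "s"))
  tr <- manual_trajectory_set(X, c("a", "a", "b"), c(0L, 1L, 0L),
                              c(0L, 0L, 1L), c(0, 1, -1),
                              c(FALSE, TRUE, TRUE), gamma = 1)
  pe <- matrix(0.2, 3, 5); pe[, 1] <- 0.4; pe <- pe / rowSums(pe)
  pb <- matrix(0.2, 3, 5)
  w <- importance_weights(tr, pe, pb, c = Inf)
  ratio <- (0.4 / 1.2) / 0.2
  expect_equal(w, c(ratio^2, 0.2 / 0.2 * (0.2 / 1.2) / 0.2), tolerance = 1e-12)
})

test_that("the concentration bound is exact on a degenerate sample and ordered in delta", {
  x <- rep(0.4, 50)
  expect_equal(hcope_lower_bound(x, method = "concentration"), 0.4)
  set.seed(2); y <- rnorm(100, 0.3, 0.2)
  b05 <- hcope_lower_bound(y, delta = 0.05)
  b10 <- hcope_lower_bound(y, delta = 0.10)
  expect_lte(b05, b10)
  expect_lte(b05, mean(y))
  expect_error(hcope_lower_bound(rnorm(10)), "at least 30")
})

test_that("the t-test bound matches its closed form on a two-point sample", {
  x <- rep(c(0, 1), each = 25)
  expected <- mean(x) - qt(0.95, 49) * sd(x) / sqrt(50)
  expect_equal(hcope_lower_bound(x, method = "t_test"), expected)
})

test_that("the BCa bootstrap bound sits below the mean and above the minimum", {
  set.seed(5); x <- rbeta(200, 2, 2)
  b <- hcope_lower_bound(x, method = "bootstrap_bca", n_boot = 500)
  expect_lt(b, mean(x))
  expect_gt(b, min(x))
})

test_that("importance-weighted evaluation is unbiased on the enumerable MDP", {
  cfg <- sim_config()
  mdp <- severity_mdp(cfg)
  bmat <- behavior_action_probs(mdp$s, cfg)
  cfg_e <- sim_config(behavior = list(intercepts = c(1.0, 0.3, -0.6, -1.4, -2.2)))
  pe_mat <- behavior_action_probs(mdp$s, cfg_e)
  J_true <- true_policy_value(mdp, pe_mat)
  sim <- simulate_severity_stays(mdp, bmat, 8000, seed = 77)
  tr <- severity_trajectories(sim, gamma = 1)
  w <- importance_weights(tr, pe_mat[sim$level, ], sim$p_action, c = Inf)
  wr <- w * tr$returns
  se <- sd(wr) / sqrt(length(wr))
  expect_lt(abs(mean(wr) - J_true), 3 * se)
})

test_that("the normalized expected mortality uses the (1-J)/2 mapping", {
  expect_equal(normalized_expected_mortality(0.6, 0.2), 0.2 / 0.4)
  expect_equal(normalized_expected_mortality(1, 0.5), 0)
})

test_that("the OPE report is self-consistent when evaluating the behavior policy itself", {
  cfg <- sim_config()
  mdp <- severity_mdp(cfg)
  bmat <- behavior_action_probs(mdp$s, cfg)
  sim <- simulate_severity_stays(mdp, bmat, 500, seed = 12)
  tr <- severity_trajectories(sim, gamma = 1)
  pe <- bmat[sim$level, ]
  rep <- ope_report(tr, pe, sim$p_action)
  expect_equal(rep$point_estimate, rep$behavior_estimate, tolerance = 1e-12)
  expect_lte(rep$lower_bound_95, rep$point_estimate)
  expect_equal(rep$normalized_expected_mortality, 1, tolerance = 1e-12)
  expect_false(rep$exceeds_behavior)
})

fixed_policy_model <- function(action) {
  # actor with zero weights except a constant bias on one logit
  net <- sepsisrl:::mlp_init(c(1, 2, 5), seed = 1)
  for (l in seq_along(net$layers)) { net$layers[[l]]$W[] <- 0; net$layers[[l]]$b[] <- 0 }
  net$layers[[length(net$layers)]]$b[action + 1] <- 5
  structure(list(actor = net, feature_names = "s"), class = "actor_critic")
}

test_that("concordance outcomes count day-level mortality by stratum", {
  # 8 concordant days (2 from the non-survivor), 4 discordant days
  X <- matrix(0, 12, 1, dimnames = list(NULL, "s"))
  ids <- rep(c("s1", "s2", "d1"), each = 4)   # d1 dies
  acts <- c(rep(0L, 8), rep(1L, 4))           # model always recommends 0
  died <- rep(c(FALSE, FALSE, TRUE), each = 4)
  rew <- ifelse(seq_len(12) %% 4 == 0, ifelse(died, -1, 1), 0)
  tr <- manual_trajectory_set(X, ids, rep(0:3, 3), acts, rew,
                              rep(c(FALSE, FALSE, FALSE, TRUE), 3), gamma = 1)
  model <- fixed_policy_model(0L)
  out <- concordance_outcomes(model, tr)
  ov <- out[out$stratum == "overall", ]
  expect_equal(ov$concordant_days, 8L)
  expect_equal(ov$discordant_days, 4L)
  expect_equal(ov$concordant_mortality, 0)     # concordant days are survivors'
  expect_equal(ov$discordant_mortality, 1)     # discordant days all from d1
  # the agent never prescribes: that stratum is empty and flagged
  pres <- out[out$stratum == "agent_prescribed", ]
  expect_true(pres$empty_stratum)
  expect_true(is.na(pres$concordant_mortality))
  # an agent identical to the logged policy leaves no discordant days
  model1 <- fixed_policy_model(1L)
  tr1 <- manual_trajectory_set(X[1:4, , drop = FALSE], rep("s1", 4), 0:3,
                               rep(1L, 4), c(0, 0, 0, 1),
                               c(FALSE, FALSE, FALSE, TRUE), gamma = 1)
  out1 <- concordance_outcomes(model1, tr1)
  expect_true(out1$empty_stratum[out1$stratum == "overall"])
  expect_equal(out1$discordant_days[out1$stratum == "overall"], 0L)
})

test_that("usage curves report per-day prescription rates and midpoint doses", {
  X <- matrix(0, 4, 1, dimnames = list(NULL, "s"))
  tr <- manual_trajectory_set(X, c("a", "a", "b", "b"), c(0L, 1L, 0L, 1L),
                              c(1L, 0L, 1L, 3L), c(0, 1, 0, 1),
                              c(FALSE, TRUE, FALSE, TRUE), gamma = 1)
  model <- fixed_policy_model(0L)
  cur <- policy_comparison_curves(model, tr)
  expect_equal(cur$day_index, c(0L, 1L))
  expect_equal(cur$agent_usage_pct, c(0, 0))          # always withholds
  expect_equal(cur$clinician_usage_pct, c(100, 50))
  expect_equal(cur$clinician_mean_dose[1], 50)         # two action-1 midpoints
  expect_equal(cur$clinician_mean_dose[2], mean(c(0, 250)))
  # no rows beyond the support of the data
  expect_equal(max(cur$day_index), 1L)
})
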