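# Shared fixtures and independent oracles for the test suite.

# Exact policy evaluation on a severity_mdp by linear solve — the stated
# oracle for critic and value checks, written directly from the Bellman
# equations (gamma = 1).
exact_policy_values <- function(mdp, pol) {
  K <- length(mdp$s)
  r_term <- rowSums(pol * (1 - 2 * mdp$p_die)) * mdp$p_dis
  Pbar <- matrix(0, K, K)
  for (a in 1:5) Pbar <- Pbar + pol[, a] * mdp$P[[a]]
  solve(diag(K) - (1 - mdp$p_dis) * Pbar, r_term)
}

# deterministic severity-threshold policy: action 0 below `th`, `a` at/above
threshold_policy <- function(mdp, th, a) {
  pol <- matrix(0, length(mdp$s), 5)
  pol[, 1] <- as.numeric(mdp$s < th)
  pol[, a + 1] <- pol[, a + 1] + as.numeric(mdp$s >= th)
  pol
}

# small uniform-initial-severity configuration for enumerable-MDP tests
tiny_mdp_config <- function(n_levels = 5) {
  sim_config(n_admissions = 10, n_severity_levels = n_levels,
             severity = list(init_floor = 0, init_shape1 = 1, init_shape2 = 1))
}

# hand-built trajectory set (used by agent unit tests)
manual_trajectory_set <- function(X, ids, days, actions, rewards, terminals,
                                  gamma = 1) {
  sepsisrl:::new_trajectory_set(X = X, admission_id = ids, day_index = days,
                                action = actions, reward = rewards,
                                terminal = terminals, gamma = gamma)
}

# Trained reference agent on the default scenario, cached across test files
# (training is the expensive step; every consumer needs the same model).
.trained_cache <- new.env(parent = emptyenv())
default_trained_agent <- function() {
  if (is.null(.trained_cache$fit)) {
    cfg <- sim_config(n_admissions = 2000, seed = 5)
    mdp <- severity_mdp(cfg)
    b <- behavior_action_probs(mdp$s, cfg)
    sim <- simulate_severity_stays(mdp, b, 2000, seed = 5)
    traj <- severity_trajectories(sim, gamma = 1)
    fit <- train_actor_critic(traj, train_config(gamma = 1, epochs = 300,
                                                 seed = 1))
    .trained_cache$fit <- list(cfg = cfg, mdp = mdp, b = b, sim = sim,
                               traj = traj, model = fit$model, log = fit$log)
  }
  .trained_cache$fit
}

# small continuous cohort shared by cohort/feature/pipeline tests
.cohort_cache <- new.env(parent = emptyenv())
small_cohort <- function() {
  if (is.null(.cohort_cache$co)) {
    cfg <- sim_config(n_admissions = 250, seed = 42)
    .cohort_cache$co <- c(list(cfg = cfg), generate_cohort(cfg))
  }
  .cohort_cache$co
}
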