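# Decision-process construction: hydrocortisone-equivalent dose conversion,
# the 5-level action space, trajectory building with terminal mortality
# rewards, and the admission-level train/validation/test split.

ACTION_BIN_EDGES <- c(0, 100, 200, 300, Inf)
ACTION_BIN_MIDPOINTS <- c(0, 50, 150, 250, 350)

#' Convert a corticosteroid dose to hydrocortisone equivalents
#'
#' @param drug_name drug name(s) present in the potency registry
#' @param dose_mg administered dose(s), mg
#' @param potency potency registry (named factors), default [steroid_potency()]
#' @return hydrocortisone-equivalent dose(s), mg
#' @export
hydrocortisone_equivalent <- function(drug_name, dose_mg,
                                      potency = steroid_potency()) {
  unknown <- setdiff(unique(drug_name), names(potency))
  if (length(unknown))
    stopf("unknown corticosteroid(s): %s; registry knows: %s",
          paste(unknown, collapse = ", "), paste(names(potency), collapse = ", "))
  if (any(dose_mg < 0, na.rm = TRUE)) stopf("doses must be non-negative")
  unname(potency[drug_name] * dose_mg)
}

#' Discretize a daily hydrocortisone-equivalent dose into the 5 actions
#'
#' Action 0 is "no corticosteroids"; the dose ranges are (0, 100],
#' (100, 200], (200, 300] and over 300 mg hydrocortisone (half-open on the
#' left, closed on the right).
#'
#' @param daily_dose_mg non-negative dose(s)
#' @return integer action indices 0-4
#' @export
discretize_action <- function(daily_dose_mg) {
  if (any(is.na(daily_dose_mg)) || any(daily_dose_mg < 0))
    stopf("daily doses must be non-negative and non-missing")
  findInterval(daily_dose_mg, ACTION_BIN_EDGES, left.open = TRUE)
}

#' Daily corticosteroid action per admission-day
#'
#' Sums all corticosteroid administrations (converted to hydrocortisone
#' equivalents) within each 24 h window from sepsis onset and discretizes.
#'
#' @param events event table
#' @param episodes episode table (included episodes, with `onset_day`)
#' @param admissions admission table
#' @param potency potency registry
#' @return `data.table` (`admission_id`, `day_index`, `dose_mg`, `action`)
#'   covering every episode day (days without steroids get action 0)
#' @export
daily_steroid_dose <- function(events, episodes, admissions,
                               potency = steroid_potency()) {
  ev <- data.table::as.data.table(events)
  ep <- data.table::as.data.table(episodes)[included == TRUE]
  adm <- data.table::as.data.table(admissions)
  ster <- ev[variable_name %in% names(potency)]
  ster <- merge(ster, adm[, .(admission_id, admitted_at)], by = "admission_id")
  ster <- merge(ster, ep[, .(admission_id, onset_day)], by = "admission_id")
  ster[, day_index := as.integer(floor(as.numeric(
    difftime(timestamp, admitted_at, units = "hours")) / 24)) - onset_day]
  ster <- ster[day_index >= 0]
  ster[, hydro := hydrocortisone_equivalent(variable_name, numeric_value, potency)]
  daily <- ster[, .(dose_mg = sum(hydro)), by = .(admission_id, day_index)]
  adm[, n_days := pmax(1L, as.integer(ceiling(as.numeric(
    difftime(discharged_at, admitted_at, units = "hours")) / 24)))]
  grid <- merge(ep[, .(admission_id, onset_day)],
                adm[, .(admission_id, n_days)], by = "admission_id")
  grid <- grid[, .(day_index = seq_len(max(n_days - onset_day, 1L)) - 1L),
               by = admission_id]
  out <- merge(grid, daily, by = c("admission_id", "day_index"), all.x = TRUE)
  out[is.na(dose_mg), dose_mg := 0]
  out[, action := discretize_action(dose_mg)]
  data.table::setorder(out, admission_id, day_index)
  out[]
}

# internal constructor shared by the continuous pipeline and the simulator
new_trajectory_set <- function(X, admission_id, day_index, action, reward,
                               terminal, gamma, behavior_prob = NULL) {
  stopifnot(nrow(X) == length(action), length(action) == length(reward))
  o <- order(admission_id, day_index)
  X <- X[o, , drop = FALSE]
  admission_id <- admission_id[o]; day_index <- day_index[o]
  action <- as.integer(action[o]); reward <- reward[o]; terminal <- terminal[o]
  if (!is.null(behavior_prob)) behavior_prob <- behavior_prob[o]
  last_of_traj <- c(admission_id[-1] != admission_id[-length(admission_id)], TRUE)
  if (!all(terminal == last_of_traj))
    stopf("each trajectory must end with exactly one terminal transition")
  traj_id <- cumsum(c(TRUE, admission_id[-1] != admission_id[-length(admission_id)]))
  ret <- vapply(split(seq_along(reward), traj_id), function(ix)
    sum(gamma ^ (seq_along(ix) - 1) * reward[ix]), numeric(1))
  structure(list(X = X, feature_names = colnames(X),
                 admission_id = admission_id, day_index = day_index,
                 action = action, reward = reward, terminal = terminal,
                 behavior_prob = behavior_prob, traj_id = traj_id,
                 gamma = gamma, n_traj = max(traj_id), returns = unname(ret)),
            class = "trajectory_set")
}

#' Build MDP trajectories from daily states and actions
#'
#' Assembles one trajectory per included septic admission: states are the
#' normalized daily feature vectors, actions the discretized corticosteroid
#' doses, intermediate rewards are 0 and the terminal reward is +1 for alive
#' ICU discharge and -1 for ICU death.
#'
#' @param states normalized wide daily table (from [build_daily_states()])
#' @param actions daily action table (from [daily_steroid_dose()])
#' @param admissions admission table with `died_in_icu`
#' @param gamma discount factor (default 0.99)
#' @return object of class `trajectory_set`: state matrix `X`, per-row
#'   `admission_id`, `day_index`, `action`, `reward`, `terminal` flag,
#'   per-trajectory `returns`
#' @export
build_trajectories <- function(states, actions, admissions, gamma = 0.99) {
  st <- data.table::as.data.table(states)
  ac <- data.table::as.data.table(actions)
  adm <- data.table::as.data.table(admissions)
  died <- adm$died_in_icu[match(st$admission_id, adm$admission_id)]
  if (any(is.na(died)))
    stopf("admissions without a terminal disposition: %s",
          paste(utils::head(unique(st$admission_id[is.na(died)])), collapse = ", "))
  dt <- merge(st, ac[, .(admission_id, day_index, action)],
              by = c("admission_id", "day_index"))
  if (nrow(dt) != nrow(st))
    stopf("state and action tables do not align on admission-days")
  data.table::setorder(dt, admission_id, day_index)
  cols <- setdiff(names(dt), c("admission_id", "day_index", "action"))
  X <- as.matrix(dt[, cols, with = FALSE])
  terminal <- c(dt$admission_id[-1] != dt$admission_id[-nrow(dt)], TRUE)
  died <- adm$died_in_icu[match(dt$admission_id, adm$admission_id)]
  reward <- ifelse(terminal, ifelse(died, -1, 1), 0)
  new_trajectory_set(X, dt$admission_id, dt$day_index, dt$action, reward,
                     terminal, gamma)
}

#' Split admissions into train / validation / test
#'
#' Random admission-level partition with largest-remainder rounding, so the
#' subset sizes always sum to the cohort size (3051 admissions at 70/20/10
#' give 2136/610/305).
#'
#' @param ids admission identifiers
#' @param fractions named fractions summing to 1
#'   (default `c(train = 0.7, validation = 0.2, test = 0.1)`)
#' @param seed RNG seed; the assignment is deterministic given the seed
#' @return `data.table` (`admission_id`, `split`)
#' @export
split_admissions <- function(ids,
                             fractions = c(train = 0.7, validation = 0.2,
                                           test = 0.1),
                             seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stopf("fractions must sum to 1")
  n <- length(ids)
  if (n < sum(fractions > 0)) stopf("fewer ids than nonzero fractions")
  exact <- fractions * n
  sizes <- floor(exact)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(exact - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1
  }
  with_seed(seed, {
    perm <- sample(ids)
    split <- rep(names(fractions), times = sizes)
    out <- data.table::data.table(admission_id = perm, split = split)
    data.table::setorder(out, admission_id)
    out[]
  })
}

#' Subset a trajectory set by admission ids
#' @param traj a `trajectory_set`
#' @param ids admission ids to keep
#' @return a `trajectory_set` with only those trajectories
#' @export
subset_trajectories <- function(traj, ids) {
  keep <- traj$admission_id %in% ids
  new_trajectory_set(traj$X[keep, , drop = FALSE], traj$admission_id[keep],
                     traj$day_index[keep], traj$action[keep],
                     traj$reward[keep], traj$terminal[keep], traj$gamma,
                     behavior_prob = traj$behavior_prob[keep])
}

#' Write trajectories as JSON lines
#' @param traj a `trajectory_set`
#' @param path output file (one trajectory per line)
#' @return invisibly, `path`
#' @export
write_trajectories <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tid in seq_len(traj$n_traj)) {
    ix <- which(traj$traj_id == tid)
    line <- jsonlite::toJSON(list(
      admission_id = traj$admission_id[ix[1]],
      day_index = traj$day_index[ix],
      action = traj$action[ix],
      reward = traj$reward[ix],
      return_ = traj$returns[tid]), auto_unbox = TRUE, digits = NA)
    writeLines(line, con)
  }
  invisible(path)
}
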