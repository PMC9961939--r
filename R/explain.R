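# Explainability: layer-wise relevance propagation through the actor network
# and a random-forest behavior clone of the clinician policy, with ranking
# comparison between the two.

#' Layer-wise relevance propagation (epsilon rule) for the actor
#'
#' Decomposes the pre-softmax logit of the explained action onto the input
#' features by propagating relevance backward through the actor's layers:
#' `R_j = sum_k z_jk / (sum_j' z_j'k + eps * sign(sum_j' z_j'k)) R_k` with
#' `z_jk = activation_j * weight_jk`. Each layer's bias is treated as an
#' extra input unit, so its absorbed relevance is accounted for explicitly
#' and conservation holds exactly at `eps = 0`:
#' `sum(relevance) + bias_relevance = explained logit`.
#'
#' @param model an `actor_critic` (or a bare `mlp` used as the actor)
#' @param state a single state vector
#' @param epsilon stabilizer (default 0.01; use 0 for exact conservation)
#' @param action explained action 0-4; default: the recommended (argmax)
#'   action, whose pre-softmax logit is decomposed
#' @return list of class `relevance_vector`: `relevance` (named by feature),
#'   `bias_relevance`, `action`, `output` (the explained logit)
#' @export
lrp_relevance <- function(model, state, epsilon = 0.01, action = NULL) {
  net <- if (inherits(model, "actor_critic")) model$actor else model
  if (!inherits(net, "mlp")) stopf("unsupported model type: %s", class(model)[1])
  fw <- mlp_forward(net, rbind(state))
  logits <- drop(fw$out)
  if (is.null(action))
    action <- which.max(logits) - 1L  # ties toward the lower index
  L <- length(net$layers)
  # relevance of the top layer: the explained logit only
  R <- numeric(length(logits))
  R[action + 1L] <- logits[action + 1L]
  bias_rel <- 0
  for (l in L:1) {
    a <- drop(fw$activations[[l]])          # inputs to layer l
    W <- net$layers[[l]]$W
    b <- net$layers[[l]]$b
    z <- a * W                              # z_jk, recycled column-wise
    denom <- colSums(z) + b                 # includes the bias unit
    stab <- denom + epsilon * ifelse(denom >= 0, 1, -1)
    share <- R / stab
    share[R == 0] <- 0                      # skip dead outputs (0/0 guard)
    R_new <- as.vector(z %*% share)
    bias_rel <- bias_rel + sum(b * share)
    R <- R_new
  }
  feats <- if (inherits(model, "actor_critic")) model$feature_names else
    colnames(rbind(state))
  names(R) <- feats %||% paste0("x", seq_along(R))
  structure(list(relevance = R, bias_relevance = unname(bias_rel),
                 action = unname(action), output = unname(logits[action + 1L])),
            class = "relevance_vector")
}

#' Global feature ranking from per-state relevances
#'
#' Mean absolute relevance per feature across day-states, sorted descending;
#' ties break alphabetically by feature name.
#'
#' @param relevances a list of `relevance_vector`s or a matrix (rows =
#'   states, columns = features)
#' @return `data.table` (`feature`, `score`, `rank`)
#' @export
aggregate_relevance <- function(relevances) {
  M <- if (is.list(relevances) && !is.data.frame(relevances) &&
           inherits(relevances[[1]], "relevance_vector"))
    do.call(rbind, lapply(relevances, `[[`, "relevance"))
  else as.matrix(relevances)
  if (!nrow(M)) stopf("at least one state is required")
  score <- colMeans(abs(M))
  ord <- order(-score, names(score))
  data.table::data.table(feature = names(score)[ord],
                         score = unname(score[ord]),
                         rank = seq_along(score))
}

#' Compute LRP relevances over a dataset of states
#' @param model an `actor_critic`
#' @param X state matrix
#' @param epsilon stabilizer
#' @return matrix of relevances (rows = states)
#' @export
lrp_relevance_matrix <- function(model, X, epsilon = 0.01) {
  X <- as.matrix(X)
  t(vapply(seq_len(nrow(X)), function(i)
    lrp_relevance(model, X[i, ], epsilon = epsilon)$relevance,
    numeric(ncol(X))))
}

# ---- Behavior clone --------------------------------------------------------

#' Fit a random-forest behavior clone of the clinician policy
#'
#' A probability forest predicting the logged action from the daily state
#' vector, with class-frequency weighting. The micro-average one-vs-rest
#' multiclass AUROC is computed on the validation split.
#'
#' @param train a `trajectory_set` (training split)
#' @param valid a `trajectory_set` (validation split) for the AUROC
#' @param num_trees number of trees (default 500)
#' @param seed RNG seed
#' @return object of class `behavior_clone`: the fitted forest, normalized
#'   `importances`, `auroc_micro`, and the confusion counts on the
#'   validation split
#' @export
fit_behavior_clone <- function(train, valid = NULL, num_trees = 500L,
                               seed = 1L) {
  y <- factor(train$action, levels = 0:4)
  present <- levels(droplevels(y))
  if (length(present) < 2) stopf("behavior cloning needs at least 2 action classes")
  df <- data.frame(train$X)
  names(df) <- make.names(train$feature_names, unique = TRUE)
  cw <- 1 / table(droplevels(y))
  fit <- ranger::ranger(x = df, y = droplevels(y), probability = TRUE,
                        num.trees = num_trees, importance = "impurity",
                        class.weights = as.numeric(cw / sum(cw)),
                        seed = seed, num.threads = 1)
  imp <- fit$variable.importance
  imp <- pmax(imp, 0)
  imp <- if (sum(imp) > 0) imp / sum(imp) else imp
  names(imp) <- train$feature_names
  auroc <- NA_real_
  confusion <- NULL
  if (!is.null(valid) && nrow(valid$X)) {
    pv <- predict_clone_probs_raw(fit, valid$X, train$feature_names)
    auroc <- auroc_micro(valid$action, pv)
    pred <- max.col(pv, ties.method = "first") - 1L
    confusion <- unclass(table(factor(valid$action, levels = 0:4),
                               factor(pred, levels = 0:4)))
  }
  structure(list(forest = fit, feature_names = train$feature_names,
                 classes_present = as.integer(present),
                 importances = imp, auroc_micro = auroc,
                 confusion = confusion),
            class = "behavior_clone")
}

# raw forest probabilities expanded to all 5 action columns
predict_clone_probs_raw <- function(fit, X, feature_names) {
  df <- data.frame(as.matrix(X))
  names(df) <- make.names(feature_names, unique = TRUE)
  pr <- stats::predict(fit, data = df, num.threads = 1)$predictions
  out <- matrix(0, nrow(df), 5L, dimnames = list(NULL, paste0("a", 0:4)))
  out[, paste0("a", colnames(pr))] <- pr
  out
}

#' Predicted action probabilities of a behavior clone
#' @param clone a `behavior_clone`
#' @param X state matrix
#' @return `n x 5` probability matrix (actions 0-4)
#' @export
predict_clone_probs <- function(clone, X) {
  predict_clone_probs_raw(clone$forest, X, clone$feature_names)
}

#' Micro-average one-vs-rest multiclass AUROC
#'
#' Pools the one-vs-rest binary indicator/probability pairs of every class
#' and computes a single rank-based (Mann-Whitney) AUROC.
#'
#' @param actions integer actions 0-4
#' @param probs `n x 5` predicted probability matrix
#' @return scalar AUROC
#' @export
auroc_micro <- function(actions, probs) {
  probs <- as.matrix(probs)
  lab <- as.vector(vapply(0:4, function(a) as.numeric(actions == a),
                          numeric(length(actions))))
  sc <- as.vector(probs)
  n1 <- sum(lab == 1); n0 <- sum(lab == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(sc)
  (sum(r[lab == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Compare agent and clinician feature rankings
#'
#' Joins the agent's LRP ranking with the behavior clone's importance ranking
#' over the same feature universe and reports the Spearman rank correlation.
#'
#' @param agent_ranking output of [aggregate_relevance()]
#' @param clone a `behavior_clone` or a ranking `data.table`
#'   (`feature`, `score`, `rank`)
#' @return list of class `ranking_comparison`: joined `table` and `spearman`
#' @export
compare_rankings <- function(agent_ranking, clone) {
  ar <- data.table::as.data.table(agent_ranking)
  cr <- if (inherits(clone, "behavior_clone")) {
    ord <- order(-clone$importances, names(clone$importances))
    data.table::data.table(feature = names(clone$importances)[ord],
                           score = unname(clone$importances[ord]),
                           rank = seq_along(clone$importances))
  } else data.table::as.data.table(clone)
  if (!setequal(ar$feature, cr$feature))
    stopf("agent and clinician rankings cover different feature universes")
  joined <- merge(ar[, .(feature, agent_score = score, agent_rank = rank)],
                  cr[, .(feature, clone_score = score, clone_rank = rank)],
                  by = "feature")
  rho <- stats::cor(joined$agent_rank, joined$clone_rank, method = "spearman")
  structure(list(table = joined[order(agent_rank)], spearman = rho),
            class = "ranking_comparison")
}
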