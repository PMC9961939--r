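# Temporal-difference actor-critic on logged ICU trajectories.
#
# Two distinct multilayer perceptrons: the actor maps a state vector to 5
# action logits (softmax policy), the critic to a scalar state value. The
# critic is trained by semi-gradient TD(0) on the squared TD error; the actor
# ascends delta * grad log pi(a|s) plus an entropy bonus. Training is pure
# offline regression on logged transitions (no importance correction inside
# the update); the off-policy evaluation module quantifies the resulting
# policy instead.

# ---- Minimal MLP (tanh hidden layers, linear output) -----------------------

mlp_init <- function(sizes, seed = NULL) {
  draw <- function() {
    lapply(seq_len(length(sizes) - 1L), function(l) {
      fan_in <- sizes[l]; fan_out <- sizes[l + 1L]
      lim <- sqrt(6 / (fan_in + fan_out))
      list(W = matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out),
           b = rep(0, fan_out))
    })
  }
  layers <- if (is.null(seed)) draw() else with_seed(seed, draw())
  structure(list(layers = layers, sizes = sizes), class = "mlp")
}

# forward pass; returns output and per-layer activations for backprop/LRP
mlp_forward <- function(net, X) {
  A <- list(as.matrix(X))
  L <- length(net$layers)
  for (l in seq_len(L)) {
    Z <- A[[l]] %*% net$layers[[l]]$W +
      matrix(net$layers[[l]]$b, nrow(A[[l]]), length(net$layers[[l]]$b),
             byrow = TRUE)
    A[[l + 1L]] <- if (l < L) tanh(Z) else Z
  }
  list(out = A[[L + 1L]], activations = A)
}

# gradients of mean(sum(dOut * out)) w.r.t. parameters
mlp_backward <- function(net, activations, dOut) {
  L <- length(net$layers)
  n <- nrow(activations[[1L]])
  grads <- vector("list", L)
  delta <- as.matrix(dOut)
  for (l in L:1) {
    grads[[l]] <- list(W = crossprod(activations[[l]], delta) / n,
                       b = colMeans(delta))
    if (l > 1) {
      delta <- (delta %*% t(net$layers[[l]]$W)) * (1 - activations[[l]]^2)
    }
  }
  grads
}

# One optimizer step in the *ascent* direction of `grads`.
# `state` carries momentum (sgd) or first/second moments and step count (adam).
mlp_step <- function(net, grads, state, lr, optimizer = "adam",
                     momentum = 0.9, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (optimizer == "adam") state$t <- state$t + 1L
  for (l in seq_along(net$layers)) {
    for (p in c("W", "b")) {
      g <- grads[[l]][[p]]
      if (optimizer == "sgd") {
        state$v[[l]][[p]] <- momentum * state$v[[l]][[p]] + g
        upd <- lr * state$v[[l]][[p]]
      } else {
        state$m[[l]][[p]] <- beta1 * state$m[[l]][[p]] + (1 - beta1) * g
        state$v[[l]][[p]] <- beta2 * state$v[[l]][[p]] + (1 - beta2) * g^2
        mhat <- state$m[[l]][[p]] / (1 - beta1^state$t)
        vhat <- state$v[[l]][[p]] / (1 - beta2^state$t)
        upd <- lr * mhat / (sqrt(vhat) + eps)
      }
      net$layers[[l]][[p]] <- net$layers[[l]][[p]] + upd
    }
  }
  list(net = net, state = state)
}

mlp_opt_state <- function(net) {
  zeros <- lapply(net$layers, function(ly) list(W = ly$W * 0, b = ly$b * 0))
  list(m = zeros, v = zeros, t = 0L)
}

# ---- Actor-critic ----------------------------------------------------------

#' Training configuration for the actor-critic
#'
#' @param gamma discount factor
#' @param lr_actor,lr_critic step sizes
#' @param optimizer `"adam"` (default) or `"sgd"` (with momentum)
#' @param momentum momentum coefficient for the SGD optimizer
#' @param epochs maximum epochs (must be at least 1)
#' @param batch_size minibatch size
#' @param seed RNG seed controlling initialization and shuffling
#' @param entropy_coef entropy-bonus coefficient, decayed linearly to 0
#' @param hidden hidden-layer widths shared by both networks
#' @param patience_window,patience_tol early stop when the relative error
#'   moves less than `patience_tol` over `patience_window` epochs
#' @return a `train_config` list
#' @export
train_config <- function(gamma = 0.99, lr_actor = 3e-4, lr_critic = 1e-3,
                         optimizer = c("adam", "sgd"), momentum = 0.9,
                         epochs = 300L, batch_size = 256L,
                         seed = 1L, entropy_coef = 1e-2, hidden = c(64, 64),
                         patience_window = 25L, patience_tol = 1e-3) {
  if (epochs < 1) stopf("epochs must be at least 1")
  if (lr_actor <= 0 || lr_critic <= 0) stopf("learning rates must be positive")
  if (entropy_coef < 0) stopf("entropy_coef must be non-negative")
  structure(list(gamma = gamma, lr_actor = lr_actor, lr_critic = lr_critic,
                 optimizer = match.arg(optimizer), momentum = momentum,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 entropy_coef = entropy_coef, hidden = hidden,
                 patience_window = as.integer(patience_window),
                 patience_tol = patience_tol),
            class = "train_config")
}

#' One-step temporal-difference error
#'
#' `delta = r + gamma * V(s') - V(s)`, with `V(terminal) = 0`.
#'
#' @param transition list with `state` (numeric vector), `reward`, and
#'   `next_state` (numeric vector, or `NULL` for a terminal transition)
#' @param model an `actor_critic` model
#' @param gamma discount factor
#' @return scalar TD error
#' @export
td_error <- function(transition, model, gamma) {
  v <- as.numeric(mlp_forward(model$critic, rbind(transition$state))$out)
  v_next <- if (is.null(transition$next_state)) 0 else
    as.numeric(mlp_forward(model$critic, rbind(transition$next_state))$out)
  unname(transition$reward + gamma * v_next - v)
}

#' Train the TD actor-critic on logged trajectories
#'
#' Iterates the logged transitions in shuffled minibatches. The critic
#' descends the squared TD error (semi-gradient: the bootstrap target is
#' treated as fixed); the actor ascends `delta * grad log pi(a|s)` plus a
#' linearly decayed entropy bonus. Per epoch the log records the relative
#' error (mean critic loss divided by the epoch-1 mean critic loss, so epoch
#' 1 is 1 by definition), the argmax-policy action histogram, the concordance
#' with the logged clinician actions, and the mean TD loss. Deterministic
#' given the seed.
#'
#' @param traj a `trajectory_set` (training split)
#' @param config a [train_config()]
#' @param valid optional `trajectory_set` whose concordance is logged too
#' @return list with `model` (class `actor_critic`) and `log` (data.table)
#' @export
train_actor_critic <- function(traj, config = train_config(), valid = NULL) {
  stopifnot(inherits(traj, "trajectory_set"))
  n <- nrow(traj$X)
  if (!n) stopf("training trajectories are empty")
  d <- ncol(traj$X)
  gamma <- config$gamma
  with_seed(config$seed, {
    actor <- mlp_init(c(d, config$hidden, 5L))
    critic <- mlp_init(c(d, config$hidden, 1L))
    s_actor <- mlp_opt_state(actor)
    s_critic <- mlp_opt_state(critic)
    next_ix <- ifelse(traj$terminal, NA_integer_, seq_len(n) + 1L)
    onehot <- diag(5)[traj$action + 1L, , drop = FALSE]
    log_rows <- vector("list", config$epochs)
    loss1 <- NA_real_
    for (epoch in seq_len(config$epochs)) {
      ent_coef <- config$entropy_coef *
        (1 - (epoch - 1) / max(config$epochs - 1, 1))
      perm <- sample.int(n)
      batches <- split(perm, ceiling(seq_along(perm) / config$batch_size))
      losses <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        ix <- batches[[bi]]
        Xb <- traj$X[ix, , drop = FALSE]
        fw_v <- mlp_forward(critic, Xb)
        v_s <- drop(fw_v$out)
        nn <- next_ix[ix]
        v_next <- numeric(length(ix))
        has_next <- !is.na(nn)
        if (any(has_next))
          v_next[has_next] <- drop(mlp_forward(critic,
            traj$X[nn[has_next], , drop = FALSE])$out)
        delta <- traj$reward[ix] + gamma * v_next - v_s
        losses[bi] <- mean(delta^2)
        if (!all(is.finite(delta)))
          stopf("training diverged at epoch %d (non-finite TD error); %s",
                epoch, "reduce the learning rates or batch size")
        # critic: descend 0.5*delta^2 with fixed target -> dV = delta
        g_c <- mlp_backward(critic, fw_v$activations, cbind(delta))
        st <- mlp_step(critic, g_c, s_critic, config$lr_critic,
                       config$optimizer, config$momentum)
        critic <- st$net; s_critic <- st$state
        # actor: ascend delta*log pi(a|s) + entropy bonus
        fw_a <- mlp_forward(actor, Xb)
        pi_b <- softmax_rows(fw_a$out)
        H <- -rowSums(pi_b * log(pi_b + 1e-12))
        d_logits <- delta * (onehot[ix, , drop = FALSE] - pi_b) -
          ent_coef * pi_b * (log(pi_b + 1e-12) + H)
        g_a <- mlp_backward(actor, fw_a$activations, d_logits)
        st <- mlp_step(actor, g_a, s_actor, config$lr_actor,
                       config$optimizer, config$momentum)
        actor <- st$net; s_actor <- st$state
      }
      mean_loss <- mean(losses)
      if (epoch == 1L) loss1 <- mean_loss
      probs <- softmax_rows(mlp_forward(actor, traj$X)$out)
      rec <- max.col(probs, ties.method = "first") - 1L
      counts <- tabulate(rec + 1L, nbins = 5L)
      row <- data.table::data.table(
        epoch = epoch, relative_error = mean_loss / loss1,
        td_loss = mean_loss,
        a0 = counts[1], a1 = counts[2], a2 = counts[3], a3 = counts[4],
        a4 = counts[5],
        concordance = mean(rec == traj$action))
      if (!is.null(valid)) {
        pv <- softmax_rows(mlp_forward(actor, valid$X)$out)
        row[, concordance_valid := mean(
          (max.col(pv, ties.method = "first") - 1L) == valid$action)]
      }
      log_rows[[epoch]] <- row
      re <- vapply(log_rows[seq_len(epoch)], function(r) r$relative_error,
                   numeric(1))
      w <- config$patience_window
      if (epoch >= w + 1L &&
          diff(range(re[(epoch - w + 1L):epoch])) < config$patience_tol)
        break
    }
    model <- structure(list(actor = actor, critic = critic,
                            feature_names = traj$feature_names,
                            hidden = config$hidden, gamma = gamma),
                       class = "actor_critic")
    list(model = model,
         log = data.table::rbindlist(log_rows[!vapply(log_rows, is.null,
                                                      logical(1))]))
  })
}

#' Policy probabilities of the actor
#' @param model an `actor_critic`
#' @param X state matrix (rows in `[-1, 1]^d`)
#' @return matrix of action probabilities (columns = actions 0-4)
#' @export
policy_probs <- function(model, X) {
  p <- softmax_rows(mlp_forward(model$actor, as.matrix(X))$out)
  colnames(p) <- paste0("a", 0:4)
  p
}

#' Critic state values
#' @param model an `actor_critic`
#' @param X state matrix
#' @return numeric vector of values
#' @export
state_values <- function(model, X) drop(mlp_forward(model$critic, as.matrix(X))$out)

#' Recommended action (argmax policy)
#'
#' Ties break toward the lower (more restrictive) action index.
#'
#' @param model an `actor_critic`
#' @param X state matrix or single state vector
#' @return integer action indices 0-4
#' @export
recommend_action <- function(model, X) {
  if (is.null(dim(X))) X <- rbind(X)
  max.col(policy_probs(model, X), ties.method = "first") - 1L
}

#' Concordance between the agent and the logged clinician actions
#'
#' @param model an `actor_critic`
#' @param traj a `trajectory_set` carrying logged actions
#' @return list: `concordance` (fraction of day-states where the
#'   recommendation equals the logged action), `confusion` (5x5 counts,
#'   logged x recommended), `per_action` (agreement by logged action)
#' @export
concordance <- function(model, traj) {
  if (!nrow(traj$X)) stopf("empty trajectory set")
  rec <- recommend_action(model, traj$X)
  confusion <- table(factor(traj$action, levels = 0:4),
                     factor(rec, levels = 0:4))
  per_action <- vapply(0:4, function(a) {
    ix <- traj$action == a
    if (!any(ix)) NA_real_ else mean(rec[ix] == a)
  }, numeric(1))
  list(concordance = mean(rec == traj$action),
       confusion = unclass(confusion),
       per_action = stats::setNames(per_action, paste0("a", 0:4)))
}

#' Serialize a trained model
#'
#' Writes the architecture and flat parameter arrays as JSON so a model can
#' be reloaded without binary artifacts.
#' @param model an `actor_critic`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_model <- function(model, path) {
  pack <- function(net) lapply(net$layers, function(ly)
    list(W = as.vector(ly$W), dim = dim(ly$W), b = ly$b))
  jsonlite::write_json(list(feature_names = model$feature_names,
                            hidden = model$hidden, gamma = model$gamma,
                            actor = pack(model$actor),
                            critic = pack(model$critic)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a serialized model
#' @param path path written by [write_model()]
#' @return an `actor_critic`
#' @export
read_model <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  unpack <- function(layers) {
    ls <- lapply(seq_len(nrow_or_len(layers)), function(i) {
      ly <- if (is.data.frame(layers)) lapply(layers, `[[`, i) else layers[[i]]
      list(W = matrix(unlist(ly$W), ly$dim[1], ly$dim[2]), b = unlist(ly$b))
    })
    sizes <- c(nrow(ls[[1]]$W), vapply(ls, function(l) ncol(l$W), numeric(1)))
    structure(list(layers = ls, sizes = sizes), class = "mlp")
  }
  structure(list(actor = unpack(js$actor), critic = unpack(js$critic),
                 feature_names = js$feature_names, hidden = js$hidden,
                 gamma = js$gamma),
            class = "actor_critic")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
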