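#' Q-network architecture specification
#'
#' The feed-forward agent (`"dqn"`) is a fully connected network
#' input -> 400 -> 300 -> n_actions by default. The recurrent agent
#' (`"drqn"`) runs a fully connected stem (default 300, 512), an LSTM layer
#' (default 512 units), and a linear action-value head, letting the
#' action-value estimate condition on the whole visit history rather than
#' the current symptom state alone.
#'
#' @param kind `"dqn"` or `"drqn"`.
#' @param input_dim State dimension (symptom vocabulary size).
#' @param hidden_sizes Hidden widths of the feed-forward layers (the stem,
#'   for `drqn`).
#' @param recurrent_size LSTM width (`drqn` only).
#' @param n_actions Number of prescription-cluster actions.
#' @return A `herbrx_qspec` list.
#' @export
qnetwork_spec <- function(kind = c("dqn", "drqn"), input_dim,
                          hidden_sizes = NULL, recurrent_size = 512L,
                          n_actions = 30L) {
  kind <- match.arg(kind)
  if (is.null(hidden_sizes)) {
    hidden_sizes <- if (kind == "dqn") c(400L, 300L) else c(300L, 512L)
  }
  spec <- list(kind = kind, input_dim = as.integer(input_dim),
               hidden_sizes = as.integer(hidden_sizes),
               recurrent_size = as.integer(recurrent_size),
               n_actions = as.integer(n_actions))
  if (any(c(spec$input_dim, spec$hidden_sizes, spec$n_actions) < 1L) ||
      (kind == "drqn" && spec$recurrent_size < 1L)) {
    stop("all layer sizes must be positive", call. = FALSE)
  }
  class(spec) <- "herbrx_qspec"
  spec
}

.build_qnet <- function(spec) {
  if (spec$kind == "dqn") {
    list(mlp = mlp_new(c(spec$input_dim, spec$hidden_sizes, spec$n_actions)))
  } else {
    stem_out <- spec$hidden_sizes[length(spec$hidden_sizes)]
    list(stem = mlp_new(c(spec$input_dim, spec$hidden_sizes)),
         lstm = lstm_new(stem_out, spec$recurrent_size),
         head = mlp_new(c(spec$recurrent_size, spec$n_actions)))
  }
}

#' Initialise an agent
#'
#' @param spec A [qnetwork_spec()].
#' @param seed Integer seed for the (Glorot-uniform) weight initialisation.
#' @return A `herbrx_agent` with fields `spec`, `params`, `seed`,
#'   `episodes_trained`.
#' @export
init_agent <- function(spec, seed = 1L) {
  params <- withr::with_seed(seed, .build_qnet(spec))
  structure(list(spec = spec, params = params, seed = as.integer(seed),
                 episodes_trained = 0L, config = NULL),
            class = "herbrx_agent")
}

#' @export
print.herbrx_agent <- function(x, ...) {
  cat(sprintf("<%s agent: %d-dim state, %d actions, %s parameters, %d episodes trained>\n",
              toupper(x$spec$kind), x$spec$input_dim, x$spec$n_actions,
              format(agent_parameter_count(x), big.mark = ","),
              x$episodes_trained))
  invisible(x)
}

#' Total number of trainable parameters
#' @param agent A `herbrx_agent` (or a `herbrx_qspec`).
#' @return Integer parameter count.
#' @export
agent_parameter_count <- function(agent) {
  params <- if (inherits(agent, "herbrx_qspec")) {
    withr::with_seed(0L, .build_qnet(agent))
  } else {
    agent$params
  }
  count <- function(x) if (is.list(x)) sum(vapply(x, count, numeric(1)))
    else length(x)
  n <- 0
  for (part in params) {
    if (!is.null(part$W)) n <- n + count(part$W) + count(part$b)
    if (!is.null(part$Wx)) n <- n + length(part$Wx) + length(part$Wh) +
        length(part$b)
  }
  as.integer(n)
}

# forward pass through a (possibly recurrent) Q-net; Xs is a T-list of
# (batch x d) matrices for drqn, a (batch x d) matrix for dqn
.qnet_forward <- function(params, spec, X, context = NULL) {
  if (spec$kind == "dqn") {
    f <- mlp_forward(params$mlp, X)
    return(list(q = f$out, context = NULL, cache = f))
  }
  Xs <- if (is.list(X)) X else list(X)
  stem_caches <- lapply(Xs, function(x) mlp_forward(params$stem, x))
  feats <- lapply(stem_caches, `[[`, "out")
  lf <- lstm_forward(params$lstm, feats, context)
  head_caches <- lapply(lf$hs, function(h) mlp_forward(params$head, h))
  list(q = head_caches[[length(head_caches)]]$out,
       q_all = lapply(head_caches, `[[`, "out"),
       context = lf$state,
       cache = list(stem = stem_caches, lstm = lf, head = head_caches))
}

#' Action values for a state (or state sequence)
#'
#' For a `dqn` agent, `state` is a single state vector (or a batch matrix).
#' For a `drqn` agent, `state` may be a single state vector plus a recurrent
#' `context` (step-wise use during rollouts) or a `T x d` matrix treated as
#' an ordered sequence starting from a zero context, in which case the
#' action values at the final step are returned.
#'
#' @param agent A `herbrx_agent`.
#' @param state State vector, batch matrix, or sequence matrix (drqn).
#' @param context Optional recurrent context from a previous call (drqn).
#' @return List: `q` (numeric vector of `n_actions` values, or a matrix for
#'   batched dqn input), `context` (updated recurrent state or `NULL`).
#' @export
q_values <- function(agent, state, context = NULL) {
  spec <- agent$spec
  if (spec$kind == "dqn") {
    X <- if (is.matrix(state)) state else matrix(state, nrow = 1L)
    if (ncol(X) != spec$input_dim) stop("state dimension mismatch", call. = FALSE)
    f <- .qnet_forward(agent$params, spec, X)
    q <- if (nrow(X) == 1L) f$q[1L, ] else f$q
    return(list(q = q, context = NULL))
  }
  if (is.matrix(state)) {
    if (ncol(state) != spec$input_dim) stop("state dimension mismatch", call. = FALSE)
    Xs <- lapply(seq_len(nrow(state)), function(t)
      matrix(state[t, ], nrow = 1L))
  } else {
    if (length(state) != spec$input_dim) stop("state dimension mismatch", call. = FALSE)
    Xs <- list(matrix(state, nrow = 1L))
  }
  f <- .qnet_forward(agent$params, spec, Xs, context)
  list(q = f$q[1L, ], context = f$context)
}

#' Epsilon-greedy action selection
#'
#' With probability `1 - epsilon` the greedy action (ties to the lowest
#' action id); otherwise uniform over all actions. Uses the current RNG
#' state.
#'
#' @param agent A `herbrx_agent`.
#' @param state State vector (drqn: with optional `context`).
#' @param epsilon Exploration probability in `[0, 1]`.
#' @param context Recurrent context (drqn rollouts).
#' @return List: `action` (1-based id), `context`, `q`.
#' @export
select_action <- function(agent, state, epsilon = 0, context = NULL) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  qv <- q_values(agent, state, context)
  n <- agent$spec$n_actions
  action <- if (epsilon > 0 && stats::runif(1) < epsilon) {
    sample.int(n, 1L)
  } else {
    which.max(qv$q)  # first maximum = lowest action id
  }
  list(action = as.integer(action), context = qv$context, q = qv$q)
}

#' Training configuration for the Q-learning agents
#'
#' @param learning_rate SGD learning rate (default 0.01).
#' @param discount Reward discount in `[0, 1)` (default 0.9); a training
#'   device distinct from the reward's effect weight.
#' @param epsilon Constant exploration probability (default 0.1).
#' @param batch_size Replay minibatch size (default 32 transitions).
#' @param target_sync_interval Hard-copy the online net to the target net
#'   every this many gradient batches (default 100).
#' @param n_episodes Number of training episodes.
#' @param replay_capacity Replay buffer size (transitions / episodes).
#' @param sequence_length Truncation length for recurrent training windows.
#' @param replay_source `"mixed"` (recorded tetrads + rollout transitions),
#'   `"bank"` (recorded tetrads only; no rollouts are generated and each
#'   "episode" is `bank_steps_per_episode` gradient batches), or
#'   `"rollout"`.
#' @param bank_steps_per_episode Gradient batches per episode under
#'   `replay_source = "bank"`.
#' @param optimizer `"sgd"` (default) or `"adam"`.
#' @param grad_clip Global-norm gradient clip (numerical safeguard).
#' @param seed Integer seed covering the whole training run.
#' @return A `herbrx_train_config` list.
#' @export
train_config <- function(learning_rate = 0.01, discount = 0.9, epsilon = 0.1,
                         batch_size = 32L, target_sync_interval = 100L,
                         n_episodes = 200L, replay_capacity = 10000L,
                         sequence_length = 8L,
                         replay_source = c("mixed", "bank", "rollout"),
                         bank_steps_per_episode = 32L,
                         optimizer = c("sgd", "adam"), grad_clip = 5,
                         seed = 1L) {
  stopifnot(epsilon >= 0, epsilon <= 1, discount >= 0, discount < 1,
            batch_size >= 1, n_episodes >= 1)
  structure(list(learning_rate = learning_rate, discount = discount,
                 epsilon = epsilon, batch_size = as.integer(batch_size),
                 target_sync_interval = as.integer(target_sync_interval),
                 n_episodes = as.integer(n_episodes),
                 replay_capacity = as.integer(replay_capacity),
                 sequence_length = as.integer(sequence_length),
                 replay_source = match.arg(replay_source),
                 bank_steps_per_episode = as.integer(bank_steps_per_episode),
                 optimizer = match.arg(optimizer), grad_clip = grad_clip,
                 seed = as.integer(seed)),
            class = "herbrx_train_config")
}

#' Bundle the virtual environment pieces into one handle
#'
#' @param bank A `herbrx_tetrad_bank`.
#' @param model The `herbrx_clusters` action model.
#' @param reward_cfg A [reward_config()].
#' @param term_cfg A [termination_config()].
#' @return A `herbrx_env` list.
#' @export
virtual_env <- function(bank, model, reward_cfg = reward_config(),
                        term_cfg = termination_config()) {
  structure(list(bank = bank, model = model, reward_cfg = reward_cfg,
                 term_cfg = term_cfg),
            class = "herbrx_env")
}

# episode state from a raw state vector
.episode_from_state <- function(state, weights = NULL) {
  structure(list(current = state,
                 initial_score = symptom_score(state, weights),
                 step_count = 0L, done = FALSE, termination_reason = "none"),
            class = "herbrx_episode")
}

# one DQN gradient batch on transition tuples; returns updated nets + loss
.dqn_batch <- function(online, target, batch, cfg) {
  B <- length(batch)
  S <- do.call(rbind, lapply(batch, `[[`, "s"))
  S2 <- do.call(rbind, lapply(batch, `[[`, "s2"))
  A <- vapply(batch, `[[`, integer(1), "a")
  R <- vapply(batch, `[[`, numeric(1), "r")
  DONE <- vapply(batch, `[[`, logical(1), "done")
  qt <- mlp_forward(target$mlp, S2)$out
  y <- R + cfg$discount * ifelse(DONE, 0, apply(qt, 1L, max))
  f <- mlp_forward(online$mlp, S)
  pred <- f$out[cbind(seq_len(B), A)]
  loss <- mean((pred - y)^2)
  dOut <- matrix(0, B, ncol(f$out))
  dOut[cbind(seq_len(B), A)] <- 2 * (pred - y) / B
  g <- mlp_backward(online$mlp, f, dOut)
  list(loss = loss, grads = list(mlp = list(W = g$W, b = g$b)))
}

# one DRQN gradient batch on padded episode windows
.drqn_batch <- function(online, target, windows, cfg, spec) {
  TT <- max(vapply(windows, function(w) length(w$steps), integer(1)))
  B <- length(windows)
  d <- spec$input_dim
  Xs <- lapply(seq_len(TT), function(t) matrix(0, B, d))
  X2s <- lapply(seq_len(TT), function(t) matrix(0, B, d))
  A <- matrix(1L, B, TT); R <- matrix(0, B, TT)
  DONE <- matrix(TRUE, B, TT); MASK <- matrix(0, B, TT)
  for (b in seq_len(B)) {
    steps <- windows[[b]]$steps
    for (t in seq_along(steps)) {
      Xs[[t]][b, ] <- steps[[t]]$s
      X2s[[t]][b, ] <- steps[[t]]$s2
      A[b, t] <- steps[[t]]$a
      R[b, t] <- steps[[t]]$r
      DONE[b, t] <- steps[[t]]$done
      MASK[b, t] <- 1
    }
  }
  # target values: run the target net over the next-state sequence from a
  # zero context (truncated-history approximation)
  tf <- .qnet_forward(target, spec, X2s)
  ymax <- vapply(tf$q_all, function(q) apply(q, 1L, max), numeric(B))
  if (B == 1L) ymax <- matrix(ymax, nrow = 1L)
  Y <- R + cfg$discount * ifelse(DONE, 0, ymax)
  of <- .qnet_forward(online, spec, Xs)
  n_eff <- sum(MASK)
  dHs <- vector("list", TT)
  loss <- 0
  head_gW <- NULL; head_gb <- NULL
  for (t in seq_len(TT)) {
    q <- of$cache$head[[t]]$out
    pred <- q[cbind(seq_len(B), A[, t])]
    err <- (pred - Y[, t]) * MASK[, t]
    loss <- loss + sum(err^2)
    dq <- matrix(0, B, ncol(q))
    dq[cbind(seq_len(B), A[, t])] <- 2 * err / n_eff
    hg <- mlp_backward(online$head, of$cache$head[[t]], dq)
    if (is.null(head_gW)) { head_gW <- hg$W; head_gb <- hg$b }
    else {
      head_gW <- mapply(`+`, head_gW, hg$W, SIMPLIFY = FALSE)
      head_gb <- mapply(`+`, head_gb, hg$b, SIMPLIFY = FALSE)
    }
    dHs[[t]] <- hg$dX
  }
  loss <- loss / n_eff
  lg <- lstm_backward(online$lstm, of$cache$lstm$cache, dHs)
  stem_gW <- NULL; stem_gb <- NULL
  for (t in seq_len(TT)) {
    sg <- mlp_backward(online$stem, of$cache$stem[[t]], lg$dXs[[t]])
    if (is.null(stem_gW)) { stem_gW <- sg$W; stem_gb <- sg$b }
    else {
      stem_gW <- mapply(`+`, stem_gW, sg$W, SIMPLIFY = FALSE)
      stem_gb <- mapply(`+`, stem_gb, sg$b, SIMPLIFY = FALSE)
    }
  }
  list(loss = loss,
       grads = list(stem = list(W = stem_gW, b = stem_gb),
                    lstm = list(Wx = lg$Wx, Wh = lg$Wh, b = lg$b),
                    head = list(W = head_gW, b = head_gb)))
}

# apply one optimizer step to the online parameter set
.opt_step <- function(params, grads, cfg, opt_state) {
  if (cfg$optimizer == "adam") {
    res <- adam_step(params, grads, opt_state, cfg$learning_rate,
                     clip = cfg$grad_clip)
    return(list(params = res$params, opt_state = res$state))
  }
  list(params = sgd_step(params, grads, cfg$learning_rate, cfg$grad_clip),
       opt_state = opt_state)
}

# bank tetrads as transition tuples / per-patient episodes
.bank_transitions <- function(bank) {
  lapply(seq_len(n_tetrads(bank)), function(i)
    list(s = bank$s1[i, ], a = bank$action[i], r = bank$reward[i],
         s2 = bank$s2[i, ], done = FALSE))
}

.bank_episodes <- function(bank) {
  trans <- .bank_transitions(bank)
  unname(split(trans, bank$patient_id))
}

#' Train a Q-learning agent against the virtual environment
#'
#' Standard deep Q-learning with experience replay and a periodically
#' synchronised target network: regression target
#' `y = r + discount * max_a Q_target(s', a)` (`y = r` at episode ends),
#' squared TD-error loss, epsilon-greedy behaviour policy, uniform
#' without-replacement minibatches, one gradient batch per environment step
#' after a warm-up of `batch_size` transitions. The recurrent agent trains
#' on contiguous episode windows of `sequence_length` steps with
#' zero-initialised context and padding masked out of the loss.
#'
#' @param env A [virtual_env()] handle.
#' @param start_states Matrix of start states (rows), e.g. encoded first
#'   visits of training patients. May be `NULL` when
#'   `replay_source = "bank"`.
#' @param spec A [qnetwork_spec()].
#' @param config A [train_config()].
#' @param verbose Print a progress line every 50 episodes.
#' @return A trained `herbrx_agent`; the training curve is in
#'   `$curve` (data frame: episode, return, loss, epsilon).
#' @export
train_agent <- function(env, start_states, spec, config = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(spec, "herbrx_qspec"), inherits(config, "herbrx_train_config"))
  if (config$replay_source != "bank" &&
      (is.null(start_states) || nrow(start_states) == 0L)) {
    stop("rollout training needs non-empty start_states", call. = FALSE)
  }
  recurrent <- spec$kind == "drqn"
  withr::with_seed(config$seed, {
    online <- .build_qnet(spec)
    target <- online
    opt_state <- if (config$optimizer == "adam") adam_new(online) else NULL
    replay <- if (config$replay_source %in% c("bank", "mixed")) {
      if (recurrent) .bank_episodes(env$bank) else .bank_transitions(env$bank)
    } else {
      list()
    }
    batches_done <- 0L
    curve <- data.frame(episode = integer(0), return = numeric(0),
                        loss = numeric(0), epsilon = numeric(0))
    do_batch <- function() {
      if (recurrent) {
        n_seq <- max(1L, config$batch_size %/% config$sequence_length)
        n_seq <- min(n_seq, length(replay))
        eps_idx <- sample.int(length(replay), n_seq)
        windows <- lapply(eps_idx, function(i) {
          ep <- replay[[i]]
          if (length(ep) > config$sequence_length) {
            st <- sample.int(length(ep) - config$sequence_length + 1L, 1L)
            ep <- ep[st:(st + config$sequence_length - 1L)]
          }
          list(steps = ep)
        })
        res <- .drqn_batch(online, target, windows, config, spec)
      } else {
        idx <- sample.int(length(replay), min(config$batch_size, length(replay)))
        res <- .dqn_batch(online, target, replay[idx], config)
      }
      if (!is.finite(res$loss)) {
        stop("training diverged (non-finite loss); lower the learning rate",
             call. = FALSE)
      }
      st <- .opt_step(online, res$grads, config, opt_state)
      online <<- st$params
      opt_state <<- st$opt_state
      batches_done <<- batches_done + 1L
      if (batches_done %% config$target_sync_interval == 0L) target <<- online
      res$loss
    }
    warm <- if (recurrent) 1L else config$batch_size
    for (ep_i in seq_len(config$n_episodes)) {
      losses <- numeric(0)
      ep_return <- NA_real_
      if (config$replay_source == "bank") {
        for (b in seq_len(config$bank_steps_per_episode)) {
          losses <- c(losses, do_batch())
        }
      } else {
        s0 <- start_states[sample.int(nrow(start_states), 1L), ]
        ep_state <- .episode_from_state(s0, env$reward_cfg$symptom_weights)
        ctx <- NULL
        ep_return <- 0
        steps <- list()
        while (!ep_state$done) {
          agent_now <- structure(list(spec = spec, params = online),
                                 class = "herbrx_agent")
          sel <- select_action(agent_now, ep_state$current, config$epsilon, ctx)
          ctx <- sel$context
          stp <- env_step(ep_state, sel$action, env$bank, env$model,
                          env$reward_cfg, env$term_cfg)
          steps[[length(steps) + 1L]] <-
            list(s = ep_state$current, a = sel$action, r = stp$reward,
                 s2 = stp$state$current, done = stp$done)
          ep_state <- stp$state
          ep_return <- ep_return + stp$reward
          if (!recurrent) {
            replay[[length(replay) + 1L]] <- steps[[length(steps)]]
            if (length(replay) > config$replay_capacity) {
              replay <- replay[-1L]
            }
            if (length(replay) >= warm) losses <- c(losses, do_batch())
          }
        }
        if (recurrent) {
          replay[[length(replay) + 1L]] <- steps
          if (length(replay) > config$replay_capacity) replay <- replay[-1L]
          for (b in seq_len(length(steps))) losses <- c(losses, do_batch())
        }
      }
      curve <- rbind(curve, data.frame(
        episode = ep_i, return = ep_return,
        loss = if (length(losses)) mean(losses) else NA_real_,
        epsilon = config$epsilon))
      if (verbose && ep_i %% 50L == 0L) {
        message(sprintf("episode %d/%d  return %.2f  loss %.4f", ep_i,
                        config$n_episodes, ep_return, mean(losses)))
      }
    }
    structure(list(spec = spec, params = online, seed = config$seed,
                   episodes_trained = config$n_episodes, config = config,
                   curve = curve),
              class = "herbrx_agent")
  })
}

#' Save / load an agent checkpoint
#'
#' The checkpoint is an RDS file holding the architecture spec, weights and
#' training metadata; a JSON sidecar (`<path>.json`) records the spec and
#' config for inspection. A loaded checkpoint reproduces greedy actions
#' exactly.
#'
#' @param agent A `herbrx_agent`.
#' @param path Checkpoint path.
#' @return `path` / the agent.
#' @export
save_agent <- function(agent, path) {
  saveRDS(agent, path)
  side <- list(spec = unclass(agent$spec),
               episodes_trained = agent$episodes_trained,
               seed = agent$seed,
               config = if (!is.null(agent$config)) unclass(agent$config))
  writeLines(jsonlite::toJSON(side, auto_unbox = TRUE, null = "null"),
             paste0(path, ".json"), useBytes = TRUE)
  invisible(path)
}

#' @rdname save_agent
#' @export
load_agent <- function(path) readRDS(path)
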