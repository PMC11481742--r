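#' Uniform-random policy
#'
#' Reference policy that picks actions uniformly; used as the floor in
#' policy comparisons.
#'
#' @param n_actions Number of actions.
#' @return A `herbrx_policy` object.
#' @export
uniform_policy <- function(n_actions) {
  structure(list(kind = "uniform", n_actions = as.integer(n_actions)),
            class = "herbrx_policy")
}

# one greedy (or uniform) action; policies are herbrx_agent or herbrx_policy
.policy_act <- function(policy, state, context = NULL) {
  if (inherits(policy, "herbrx_agent")) {
    sel <- select_action(policy, state, epsilon = 0, context = context)
    return(list(action = sel$action, context = sel$context))
  }
  if (inherits(policy, "herbrx_policy") && policy$kind == "uniform") {
    return(list(action = sample.int(policy$n_actions, 1L), context = NULL))
  }
  stop("unsupported policy object", call. = FALSE)
}

#' Returns of the recorded clinician baseline
#'
#' Computes the three return metrics directly from the recorded visit
#' sequences: SSR is the mean per-step reward over each patient's first
#' consecutive visit pair, SCR the mean over all consecutive visit pairs
#' pooled (or per patient then averaged with `per_patient = TRUE`), MCR the
#' mean over patients of the summed rewards along the full recorded
#' sequence. The risk term is handled per
#' `config$doctor_jaccard_mode`: the clinician's prescription trivially has
#' Jaccard 1 with itself (`"self_one"`), or the term is excluded.
#'
#' @param cohort A multi-visit `herbrx_cohort`.
#' @param config A [reward_config()].
#' @param per_patient Average SCR within patient first.
#' @return List with `ssr`, `scr`, `mcr`.
#' @export
doctor_returns <- function(cohort, config = reward_config(),
                           per_patient = FALSE) {
  if (length(cohort$patients) == 0L) stop("empty cohort", call. = FALSE)
  if (any(visit_counts(cohort) < 2L)) {
    stop("doctor baseline needs >= 2 visits per patient", call. = FALSE)
  }
  cfg <- config
  if (config$doctor_jaccard_mode == "excluded") cfg$risk_weight <- 0
  first_rewards <- numeric(0)
  all_rewards_by_patient <- list()
  for (p in cohort$patients) {
    states <- lapply(p$visits, encode_state, vocab = cohort$symptom_vocab)
    rs <- vapply(seq_len(length(p$visits) - 1L), function(t) {
      reward(states[[t]], states[[t + 1L]], p$visits[[t]]$herbs,
             p$visits[[t]]$herbs, cfg)
    }, numeric(1))
    first_rewards <- c(first_rewards, rs[1L])
    all_rewards_by_patient[[length(all_rewards_by_patient) + 1L]] <- rs
  }
  pooled <- unlist(all_rewards_by_patient)
  list(ssr = mean(first_rewards),
       scr = if (per_patient) {
         mean(vapply(all_rewards_by_patient, mean, numeric(1)))
       } else {
         mean(pooled)
       },
       mcr = mean(vapply(all_rewards_by_patient, sum, numeric(1))))
}

# greedy one-step reward from a given recorded visit state
.one_step_reward <- function(policy, state, env, context = NULL) {
  ep <- .episode_from_state(state, env$reward_cfg$symptom_weights)
  act <- .policy_act(policy, state, context)
  stp <- env_step(ep, act$action, env$bank, env$model, env$reward_cfg,
                  env$term_cfg)
  list(reward = stp$reward, context = act$context)
}

#' Single-step return of a policy
#'
#' Mean one-step reward from each test patient's first-visit state under the
#' policy's greedy action.
#'
#' @param policy A trained `herbrx_agent` or [uniform_policy()].
#' @param cohort Test `herbrx_cohort`.
#' @param env A [virtual_env()].
#' @param seed Optional seed (stochastic policies only).
#' @return Numeric SSR.
#' @export
policy_ssr <- function(policy, cohort, env, seed = NULL) {
  run <- function() {
    mean(vapply(cohort$patients, function(p) {
      s <- encode_state(p$visits[[1L]], cohort$symptom_vocab)
      .one_step_reward(policy, s, env)$reward
    }, numeric(1)))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Single-step cumulative return of a policy
#'
#' One-step greedy rewards from every recorded visit state except each
#' patient's last, pooled over all such steps. A recurrent agent's context
#' is advanced along the recorded state history, so mid-sequence decisions
#' condition on the visits that actually preceded them.
#'
#' @inheritParams policy_ssr
#' @param per_patient Average within patient before averaging patients.
#' @return Numeric SCR.
#' @export
policy_scr <- function(policy, cohort, env, per_patient = FALSE, seed = NULL) {
  run <- function() {
    per <- lapply(cohort$patients, function(p) {
      n <- length(p$visits)
      ctx <- NULL
      vapply(seq_len(n - 1L), function(t) {
        s <- encode_state(p$visits[[t]], cohort$symptom_vocab)
        res <- .one_step_reward(policy, s, env, ctx)
        ctx <<- res$context
        res$reward
      }, numeric(1))
    })
    if (per_patient) mean(vapply(per, mean, numeric(1))) else mean(unlist(per))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Multi-step cumulative return of a policy
#'
#' Greedy rollout from each test patient's first-visit state through the
#' virtual environment until a termination rule fires; MCR is the mean over
#' patients of the summed (undiscounted) rewards.
#'
#' @inheritParams policy_ssr
#' @return List: `mcr`, `rollouts` (per patient: `patient_id`, `states`
#'   matrix, `actions`, `rewards`, `termination_reason`).
#' @export
policy_mcr <- function(policy, cohort, env, seed = NULL) {
  run <- function() {
    rollouts <- lapply(cohort$patients, function(p) {
      s <- encode_state(p$visits[[1L]], cohort$symptom_vocab)
      ep <- .episode_from_state(s, env$reward_cfg$symptom_weights)
      states <- list(s); actions <- integer(0); rewards <- numeric(0)
      ctx <- NULL
      while (!ep$done) {
        act <- .policy_act(policy, ep$current, ctx)
        ctx <- act$context
        stp <- env_step(ep, act$action, env$bank, env$model, env$reward_cfg,
                        env$term_cfg)
        ep <- stp$state
        states[[length(states) + 1L]] <- ep$current
        actions <- c(actions, act$action)
        rewards <- c(rewards, stp$reward)
      }
      list(patient_id = p$patient_id, states = do.call(rbind, states),
           actions = actions, rewards = rewards,
           termination_reason = ep$termination_reason)
    })
    list(mcr = mean(vapply(rollouts, function(r) sum(r$rewards), numeric(1))),
         rollouts = rollouts)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Sequence-length statistics of rollouts vs recorded care
#'
#' @param rollouts Rollout list from [policy_mcr()].
#' @param doctor Recorded `herbrx_cohort` for the baseline mean visit count.
#' @return List: `policy_mean_length` (mean number of actions per rollout)
#'   and `doctor_mean_length` (mean recorded visits per patient).
#' @export
sequence_length_stats <- function(rollouts, doctor) {
  stopifnot(length(rollouts) > 0L)
  list(policy_mean_length = mean(vapply(rollouts, function(r)
    length(r$actions), numeric(1))),
       doctor_mean_length = mean(visit_counts(doctor)))
}

#' Relative improvement of a model value over a baseline
#'
#' @param model_value,baseline_value Numeric scalars; `baseline_value != 0`.
#' @return Percentage `100 * (model - baseline) / baseline` (full
#'   precision; round for display).
#' @export
improvement_rate <- function(model_value, baseline_value) {
  if (baseline_value == 0) stop("baseline value is zero", call. = FALSE)
  100 * (model_value - baseline_value) / baseline_value
}

#' Tabulate policy returns with improvement rates over the baseline
#'
#' @param values Named list of per-policy lists with `ssr`, `scr`, `mcr`;
#'   the first entry is the baseline (typically the clinician).
#' @return Data frame: policy, ssr, scr, mcr, and `*_improvement_pct`
#'   columns relative to the baseline (NA for the baseline row).
#' @export
return_report <- function(values) {
  stopifnot(length(values) >= 1L, !is.null(names(values)))
  base <- values[[1L]]
  rows <- lapply(seq_along(values), function(i) {
    v <- values[[i]]
    data.frame(policy = names(values)[i], ssr = v$ssr, scr = v$scr,
               mcr = v$mcr,
               ssr_improvement_pct = if (i == 1L) NA_real_ else
                 improvement_rate(v$ssr, base$ssr),
               scr_improvement_pct = if (i == 1L) NA_real_ else
                 improvement_rate(v$scr, base$scr),
               mcr_improvement_pct = if (i == 1L) NA_real_ else
                 improvement_rate(v$mcr, base$mcr),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
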