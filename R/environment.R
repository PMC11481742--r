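#' Reward configuration
#'
#' The per-step reward is
#' `effect_weight * sum_i alpha_i (s_i - s'_i) + risk_weight * Jac(a, a')`:
#' a therapeutic-effect term (weighted symptom-score drop between
#' consecutive states) plus a risk-containment term rewarding similarity of
#' the proposed herb set to the clinician's recorded one. Symptom grading is
#' hard to obtain, so all symptom weights default to 1 and the score is
#' simply the symptom count.
#'
#' @param effect_weight Weight of the therapeutic-effect term (>= 0).
#' @param risk_weight Weight of the Jaccard risk term (>= 0).
#' @param symptom_weights Per-symptom weights `alpha`; `NULL` means unit
#'   weights.
#' @param doctor_jaccard_mode How the clinician baseline scores its own risk
#'   term: `"self_one"` (Jaccard of a prescription with itself, i.e. 1) or
#'   `"excluded"` (risk term dropped from baseline returns).
#' @return A `herbrx_reward_config` list.
#' @export
reward_config <- function(effect_weight = 1.0, risk_weight = 1.0,
                          symptom_weights = NULL,
                          doctor_jaccard_mode = c("self_one", "excluded")) {
  if (effect_weight < 0 || risk_weight < 0) {
    stop("weights must be non-negative", call. = FALSE)
  }
  structure(list(effect_weight = effect_weight, risk_weight = risk_weight,
                 symptom_weights = symptom_weights,
                 doctor_jaccard_mode = match.arg(doctor_jaccard_mode)),
            class = "herbrx_reward_config")
}

#' Weighted symptom score of a state
#'
#' With unit weights this is the number of present symptoms, the proxy used
#' for disease severity.
#'
#' @param state Binary state vector.
#' @param weights Optional per-symptom weights; `NULL` = all 1.
#' @return Numeric score.
#' @export
symptom_score <- function(state, weights = NULL) {
  if (is.null(weights)) return(sum(state))
  if (length(weights) != length(state)) {
    stop("weights and state have different lengths", call. = FALSE)
  }
  sum(weights * state)
}

#' Jaccard similarity of two sets
#'
#' `|a intersect b| / |a union b|`; two empty sets score 1, an empty set
#' against a non-empty one scores 0.
#'
#' @param a,b Vectors treated as sets.
#' @return Numeric in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' Per-step reward
#'
#' @param s,s_next Binary state vectors (same length).
#' @param doctor_herbs Herb set recorded by the clinician for this step.
#' @param predicted_herbs Herb set proposed by the policy.
#' @param config A [reward_config()].
#' @return Numeric reward.
#' @export
reward <- function(s, s_next, doctor_herbs, predicted_herbs, config) {
  if (length(s) != length(s_next)) {
    stop("state dimension mismatch", call. = FALSE)
  }
  eff <- symptom_score(s, config$symptom_weights) -
    symptom_score(s_next, config$symptom_weights)
  config$effect_weight * eff +
    config$risk_weight * jaccard(doctor_herbs, predicted_herbs)
}

#' Build the tetrad bank from a multi-visit cohort
#'
#' Every consecutive visit pair of every patient becomes one transition
#' tetrad `(s1, a, r, s2)`: `s1`/`s2` are the binary symptom states, the
#' action is the cluster of the visit's recorded prescription, and the
#' reward is computed with the recorded herbs standing in for the predicted
#' ones (so the Jaccard term is 1 when `risk_weight > 0`). The bank of
#' tetrads is the offline virtual environment the agents train against.
#'
#' @param cohort A multi-visit `herbrx_cohort` (see [filter_multivisit()]).
#' @param model A `herbrx_clusters` model covering the cohort's
#'   prescriptions.
#' @param config A [reward_config()].
#' @return A `herbrx_tetrad_bank`: `s1`, `s2` (matrices, one row per
#'   tetrad), `action`, `reward`, `doctor_herbs` (list), `patient_id`,
#'   `visit_index`, `by_action` (positions per action), `symptom_vocab`.
#' @export
build_tetrads <- function(cohort, model, config = reward_config()) {
  if (any(visit_counts(cohort) < 2L)) {
    stop("cohort contains single-visit patients; apply filter_multivisit() first",
         call. = FALSE)
  }
  if (length(cohort$patients) == 0L) stop("empty cohort", call. = FALSE)
  d <- length(cohort$symptom_vocab)
  s1 <- list(); s2 <- list(); action <- integer(0); rew <- numeric(0)
  dh <- list(); pid <- character(0); vix <- integer(0)
  for (p in cohort$patients) {
    states <- lapply(p$visits, encode_state, vocab = cohort$symptom_vocab)
    for (t in seq_len(length(p$visits) - 1L)) {
      v <- p$visits[[t]]
      a <- assign_cluster(model, v$herbs)
      r <- reward(states[[t]], states[[t + 1L]], v$herbs, v$herbs, config)
      s1[[length(s1) + 1L]] <- states[[t]]
      s2[[length(s2) + 1L]] <- states[[t + 1L]]
      action <- c(action, a); rew <- c(rew, r)
      dh[[length(dh) + 1L]] <- v$herbs
      pid <- c(pid, p$patient_id); vix <- c(vix, v$visit_index)
    }
  }
  bank <- structure(
    list(s1 = do.call(rbind, s1), s2 = do.call(rbind, s2),
         action = action, reward = rew, doctor_herbs = dh,
         patient_id = pid, visit_index = vix,
         by_action = split(seq_along(action), action),
         symptom_vocab = cohort$symptom_vocab),
    class = "herbrx_tetrad_bank")
  bank
}

#' @export
print.herbrx_tetrad_bank <- function(x, ...) {
  cat(sprintf("<tetrad bank: %d tetrads, %d actions, state dim %d>\n",
              length(x$action), length(x$by_action), ncol(x$s1)))
  invisible(x)
}

#' Number of tetrads in a bank
#' @param bank A `herbrx_tetrad_bank`.
#' @return Integer count.
#' @export
n_tetrads <- function(bank) length(bank$action)

#' Predict the next state by Jaccard nearest neighbour
#'
#' Among the bank tetrads carrying the queried action, the one whose `s1`
#' symptom set is most Jaccard-similar to the current state is matched and
#' its `s2` returned. Ties break to the lowest tetrad index; if no tetrad
#' carries the action, the globally nearest tetrad is used (flagged in the
#' result).
#'
#' @param state Binary state vector.
#' @param action Cluster id (1-based).
#' @param bank A `herbrx_tetrad_bank`.
#' @return List: `next_state`, `index` (matched tetrad position),
#'   `similarity`, `doctor_herbs` of the matched tetrad, `reward` (its
#'   stored reward), `fallback` (logical: action absent from bank).
#' @export
predict_transition <- function(state, action, bank) {
  if (n_tetrads(bank) == 0L) stop("empty tetrad bank", call. = FALSE)
  cand <- bank$by_action[[as.character(action)]]
  fallback <- is.null(cand) || length(cand) == 0L
  if (fallback) cand <- seq_len(n_tetrads(bank))
  s1 <- bank$s1[cand, , drop = FALSE]
  inter <- as.numeric(s1 %*% state)
  uni <- rowSums(s1) + sum(state) - inter
  sim <- ifelse(uni == 0, 1, inter / uni)
  best <- cand[which.max(sim)]  # which.max = first maximum = lowest index
  list(next_state = bank$s2[best, ], index = best,
       similarity = max(sim), doctor_herbs = bank$doctor_herbs[[best]],
       reward = bank$reward[best], fallback = fallback)
}

#' Termination rules for simulated treatment sequences
#'
#' Three stopping conditions: absolute symptom score at or below
#' `score_threshold`; relative score reduction of at least
#' `reduction_fraction` from the initial visit (between the 30% "effective"
#' and 70% "markedly effective" clinical criteria); or more than `max_steps`
#' treatment iterations.
#'
#' @param score_threshold Absolute score stop (default 3).
#' @param reduction_fraction Relative reduction stop (default 0.6).
#' @param max_steps Iteration cap (default 15).
#' @return A `herbrx_term_config` list.
#' @export
termination_config <- function(score_threshold = 3, reduction_fraction = 0.6,
                               max_steps = 15L) {
  if (!(reduction_fraction > 0 && reduction_fraction < 1)) {
    stop("reduction_fraction must be in (0, 1)", call. = FALSE)
  }
  if (max_steps < 1L) stop("max_steps must be >= 1", call. = FALSE)
  structure(list(score_threshold = score_threshold,
                 reduction_fraction = reduction_fraction,
                 max_steps = as.integer(max_steps)),
            class = "herbrx_term_config")
}

#' Evaluate the termination rules on an episode state
#'
#' Rules are checked in fixed order — absolute score, relative reduction,
#' iteration cap — so the reported reason is deterministic when several hold
#' at once.
#'
#' @param ep An episode state as returned by [env_reset()]/[env_step()].
#' @param config A [termination_config()].
#' @param weights Optional symptom weights for scoring.
#' @return List `done` (logical) and `reason` (`"score_low"`, `"reduced"`,
#'   `"max_steps"` or `"none"`).
#' @export
is_terminal <- function(ep, config, weights = NULL) {
  score <- symptom_score(ep$current, weights)
  if (score <= config$score_threshold) {
    return(list(done = TRUE, reason = "score_low"))
  }
  if (score <= (1 - config$reduction_fraction) * ep$initial_score) {
    return(list(done = TRUE, reason = "reduced"))
  }
  if (ep$step_count > config$max_steps) {
    return(list(done = TRUE, reason = "max_steps"))
  }
  list(done = FALSE, reason = "none")
}

#' Start a simulated treatment episode
#'
#' @param first_visit A `herbrx_visit` (the patient's first recorded visit)
#'   or a plain character vector of symptom terms.
#' @param vocab The symptom vocabulary.
#' @param weights Optional symptom weights.
#' @return A `herbrx_episode` state: `current`, `initial_score`,
#'   `step_count = 0`, `done = FALSE`, `termination_reason = "none"`.
#' @export
env_reset <- function(first_visit, vocab, weights = NULL) {
  s <- encode_state(first_visit, vocab)
  structure(list(current = s,
                 initial_score = symptom_score(s, weights),
                 step_count = 0L, done = FALSE,
                 termination_reason = "none"),
            class = "herbrx_episode")
}

#' Advance a simulated treatment episode by one action
#'
#' The next state comes from [predict_transition()]; the reward is recomputed
#' from the observed transition with the acting policy's herb set (the
#' chosen cluster's representative) against the matched tetrad's recorded
#' clinician herbs — or, with `use_stored_reward = TRUE`, the matched
#' tetrad's stored reward is reused. Termination is evaluated on the new
#' state after incrementing the step count.
#'
#' @param ep A live `herbrx_episode`.
#' @param action Cluster id (1-based).
#' @param bank A `herbrx_tetrad_bank`.
#' @param model The `herbrx_clusters` model supplying representatives.
#' @param reward_cfg A [reward_config()].
#' @param term_cfg A [termination_config()].
#' @param use_stored_reward Reuse the matched tetrad's stored reward instead
#'   of recomputing from the realised transition.
#' @return List: `state` (updated episode), `reward`, `done`, `info`
#'   (matched tetrad index, similarity, fallback flag).
#' @export
env_step <- function(ep, action, bank, model, reward_cfg = reward_config(),
                     term_cfg = termination_config(),
                     use_stored_reward = FALSE) {
  if (ep$done) stop("cannot step a finished episode", call. = FALSE)
  tr <- predict_transition(ep$current, action, bank)
  r <- if (use_stored_reward) {
    tr$reward
  } else {
    reward(ep$current, tr$next_state, tr$doctor_herbs,
           cluster_representative(model, action), reward_cfg)
  }
  ep$current <- tr$next_state
  ep$step_count <- ep$step_count + 1L
  term <- is_terminal(ep, term_cfg, reward_cfg$symptom_weights)
  ep$done <- term$done
  ep$termination_reason <- term$reason
  list(state = ep, reward = r, done = term$done,
       info = list(index = tr$index, similarity = tr$similarity,
                   fallback = tr$fallback))
}

#' Persist / load a tetrad bank as JSONL (states as 1-based index lists)
#' @param bank A `herbrx_tetrad_bank`.
#' @param path File path.
#' @export
write_tetrads <- function(bank, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  header <- jsonlite::toJSON(
    list(symptom_vocab = unclass(bank$symptom_vocab)), digits = NA)
  lines <- vapply(seq_len(n_tetrads(bank)), function(i) {
    jsonlite::toJSON(list(
      s1 = which(bank$s1[i, ] != 0), a = jsonlite::unbox(bank$action[i]),
      r = jsonlite::unbox(bank$reward[i]), s2 = which(bank$s2[i, ] != 0),
      doctor_herbs = bank$doctor_herbs[[i]],
      patient_id = jsonlite::unbox(bank$patient_id[i]),
      visit_index = jsonlite::unbox(bank$visit_index[i])), digits = NA)
  }, character(1))
  writeLines(c(header, lines), con, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_tetrads
#' @export
read_tetrads <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vocab <- vocabulary(jsonlite::fromJSON(lines[[1]])$symptom_vocab)
  d <- length(vocab)
  recs <- lapply(lines[-1], jsonlite::fromJSON)
  tovec <- function(idx) { v <- numeric(d); v[idx] <- 1; v }
  structure(
    list(s1 = do.call(rbind, lapply(recs, function(r) tovec(r$s1))),
         s2 = do.call(rbind, lapply(recs, function(r) tovec(r$s2))),
         action = vapply(recs, function(r) as.integer(r$a), integer(1)),
         reward = vapply(recs, function(r) as.numeric(r$r), numeric(1)),
         doctor_herbs = lapply(recs, function(r) as.character(r$doctor_herbs)),
         patient_id = vapply(recs, function(r) as.character(r$patient_id),
                             character(1)),
         visit_index = vapply(recs, function(r) as.integer(r$visit_index),
                              integer(1)),
         by_action = split(seq_along(recs),
                           vapply(recs, function(r) as.integer(r$a), integer(1))),
         symptom_vocab = vocab),
    class = "herbrx_tetrad_bank")
}
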