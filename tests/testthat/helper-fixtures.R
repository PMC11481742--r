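# shared in-code fixtures

# cohort from a compact description: list of per-patient visit lists,
# each visit a list(symptoms=..., herbs=...)
mk_cohort <- function(spec_list, symptom_vocab = NULL, herb_vocab = NULL) {
  patients <- lapply(seq_along(spec_list), function(i) {
    visits <- lapply(seq_along(spec_list[[i]]), function(t) {
      v <- spec_list[[i]][[t]]
      visit_record(sprintf("p%02d", i), t - 1L, v$symptoms, v$herbs)
    })
    patient_sequence(sprintf("p%02d", i), visits)
  })
  cohort(patients, symptom_vocab, herb_vocab)
}

# a patient whose visit symptom counts follow `scores`, using distinct
# symptom terms sN; herbs constant
mk_score_patient <- function(id, scores, herbs = c("hA", "hB")) {
  visits <- lapply(seq_along(scores), function(t) {
    visit_record(id, t - 1L, paste0("s", seq_len(scores[t])), herbs)
  })
  patient_sequence(id, visits)
}

# deterministic 2-state / 2-action chain MDP embedded as a tetrad bank:
# state x: action 1 stays (r 0), action 2 -> y (r 1)
# state y: action 1 -> x (r 1), action 2 stays (r 0)
mk_chain_bank <- function() {
  s1m <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  s2m <- rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1))
  a <- c(1L, 2L, 1L, 2L)
  r <- c(0, 1, 1, 0)
  structure(list(s1 = s1m, s2 = s2m, action = a, reward = r,
                 doctor_herbs = replicate(4, "h", simplify = FALSE),
                 patient_id = c("p1", "p1", "p2", "p2"),
                 visit_index = c(0L, 1L, 0L, 1L),
                 by_action = split(seq_along(a), a),
                 symptom_vocab = vocabulary(c("x", "y"))),
            class = "herbrx_tetrad_bank")
}

# value iteration on the chain MDP above
chain_mdp_oracle <- function(discount = 0.9, iters = 2000L) {
  q <- matrix(0, 2, 2)  # rows: states x, y; cols: actions
  r <- rbind(c(0, 1), c(1, 0))
  nxt <- rbind(c(1L, 2L), c(1L, 2L))  # next state index
  for (i in seq_len(iters)) {
    v <- apply(q, 1L, max)
    q <- r + discount * rbind(v[nxt[1L, ]], v[nxt[2L, ]])
  }
  q
}

# random tetrad bank over binary states
random_bank <- function(n, d, n_actions, seed) {
  withr::with_seed(seed, {
    s1 <- matrix(rbinom(n * d, 1L, 0.25), n, d)
    s1[rowSums(s1) == 0, 1L] <- 1L
    s2 <- matrix(rbinom(n * d, 1L, 0.25), n, d)
    a <- sample.int(n_actions, n, replace = TRUE)
    structure(list(s1 = s1, s2 = s2, action = a,
                   reward = rnorm(n),
                   doctor_herbs = replicate(n, sample(letters, 3), simplify = FALSE),
                   patient_id = sprintf("p%d", seq_len(n)),
                   visit_index = rep(0L, n),
                   by_action = split(seq_len(n), a),
                   symptom_vocab = vocabulary(sprintf("s%03d", seq_len(d)))),
              class = "herbrx_tetrad_bank")
  })
}

# fake cluster model exposing only what pairwise_cluster_difference needs
mk_fake_clusters <- function(assignment, k) {
  structure(list(k = as.integer(k), assignment = as.integer(assignment)),
            class = "herbrx_clusters")
}

# prescription "matrix" whose rows are one-hot herbs with given multiplicity
mk_onehot_matrix <- function(counts_by_cluster) {
  H <- ncol(counts_by_cluster)
  rows <- list(); mult <- integer(0); assign <- integer(0)
  for (cl in seq_len(nrow(counts_by_cluster))) {
    for (h in seq_len(H)) {
      if (counts_by_cluster[cl, h] > 0) {
        v <- numeric(H); v[h] <- 1
        rows[[length(rows) + 1L]] <- v
        mult <- c(mult, counts_by_cluster[cl, h])
        assign <- c(assign, cl)
      }
    }
  }
  mat <- structure(list(x = do.call(rbind, rows), multiplicity = mult,
                        keys = as.character(seq_along(mult)),
                        herb_vocab = vocabulary(sprintf("h%d", seq_len(H)))),
                   class = "herbrx_rx_matrix")
  list(matrix = mat, model = mk_fake_clusters(assign, nrow(counts_by_cluster)))
}

# textbook chi-square -log10 p on a 2 x H count table (independent oracle)
oracle_chisq_neglog10p <- function(tab, clip = 300) {
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  mlp <- -stats::pchisq(unname(ct$statistic), unname(ct$parameter),
                        lower.tail = FALSE, log.p = TRUE) / log(10)
  min(mlp, clip)
}
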