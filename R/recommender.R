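#' Recommender architecture specification
#'
#' A fully connected multi-label network mapping a patient's binary symptom
#' vector — optionally concatenated with a one-hot prescription-cluster
#' block (the planned treatment scheme) — to independent per-herb
#' probabilities (sigmoid outputs, binary cross-entropy loss).
#'
#' @param input_mode `"symptom"` or `"symptom_plus_scheme"`.
#' @param n_symptoms Symptom vocabulary size.
#' @param n_herbs Herb vocabulary size (output dimension).
#' @param n_clusters Number of clusters (scheme one-hot width; required for
#'   `symptom_plus_scheme`).
#' @param hidden_sizes Hidden layer widths (default `c(256, 128)`, i.e. a
#'   three-layer fully connected net).
#' @return A `herbrx_rec_spec` list.
#' @export
recommender_spec <- function(input_mode = c("symptom", "symptom_plus_scheme"),
                             n_symptoms, n_herbs, n_clusters = NULL,
                             hidden_sizes = c(256L, 128L)) {
  input_mode <- match.arg(input_mode)
  if (input_mode == "symptom_plus_scheme" && is.null(n_clusters)) {
    stop("symptom_plus_scheme mode needs n_clusters", call. = FALSE)
  }
  input_dim <- as.integer(n_symptoms) +
    if (input_mode == "symptom_plus_scheme") as.integer(n_clusters) else 0L
  structure(list(input_mode = input_mode,
                 n_symptoms = as.integer(n_symptoms),
                 n_herbs = as.integer(n_herbs),
                 n_clusters = if (is.null(n_clusters)) NULL else
                   as.integer(n_clusters),
                 input_dim = input_dim,
                 hidden_sizes = as.integer(hidden_sizes)),
            class = "herbrx_rec_spec")
}

#' Feature vector for one visit
#'
#' Binary symptom block, then (in scheme mode) a one-hot block for the
#' planned prescription cluster.
#'
#' @param record A `herbrx_visit` (or character vector of symptoms).
#' @param hpc Planned cluster id (1-based) or `NULL` in symptom-only mode.
#' @param vocab Symptom vocabulary.
#' @param spec A [recommender_spec()].
#' @return Numeric feature vector of length `spec$input_dim`.
#' @export
build_features <- function(record, hpc, vocab, spec) {
  sym <- encode_state(record, vocab)
  if (spec$input_mode == "symptom") return(sym)
  if (is.null(hpc)) {
    stop("scheme mode requires a planned cluster id", call. = FALSE)
  }
  onehot <- numeric(spec$n_clusters)
  onehot[as.integer(hpc)] <- 1
  c(sym, onehot)
}

#' Train the multi-label herb recommender
#'
#' Sigmoid outputs with binary cross-entropy, Adam updates on uniformly
#' shuffled minibatches. Reproducible given `seed`.
#'
#' @param features Numeric matrix (samples x `spec$input_dim`).
#' @param targets Binary matrix (samples x `spec$n_herbs`) of herb
#'   membership.
#' @param spec A [recommender_spec()].
#' @param epochs Training epochs (default 60).
#' @param learning_rate Adam learning rate (default 0.01).
#' @param batch_size Minibatch size (default 32).
#' @param seed Integer seed.
#' @return A `herbrx_recommender`: `spec`, `net`, `loss_curve`.
#' @export
train_recommender <- function(features, targets, spec, epochs = 60L,
                              learning_rate = 0.01, batch_size = 32L,
                              seed = 1L) {
  stopifnot(nrow(features) == nrow(targets), nrow(features) > 0L,
            ncol(features) == spec$input_dim, ncol(targets) == spec$n_herbs)
  withr::with_seed(seed, {
    net <- mlp_new(c(spec$input_dim, spec$hidden_sizes, spec$n_herbs),
                   out_activation = "sigmoid")
    opt <- adam_new(list(W = net$W, b = net$b))
    n <- nrow(features)
    loss_curve <- numeric(epochs)
    for (e in seq_len(epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        X <- features[idx, , drop = FALSE]
        Y <- targets[idx, , drop = FALSE]
        f <- mlp_forward(net, X)
        p <- pmin(pmax(f$out, 1e-12), 1 - 1e-12)
        loss <- -mean(Y * log(p) + (1 - Y) * log(1 - p))
        if (!is.finite(loss)) {
          stop("recommender training diverged (non-finite loss)", call. = FALSE)
        }
        losses <- c(losses, loss)
        # BCE through sigmoid: delta at the pre-activation is (p - y)/n
        dOut <- (f$out - Y) / length(Y)
        g <- mlp_backward(net, f, dOut, from_logits = TRUE)
        st <- adam_step(list(W = net$W, b = net$b), list(W = g$W, b = g$b),
                        opt, learning_rate)
        net$W <- st$params$W; net$b <- st$params$b
        opt <- st$state
      }
      loss_curve[e] <- mean(losses)
    }
    structure(list(spec = spec, net = net, loss_curve = loss_curve),
              class = "herbrx_recommender")
  })
}

#' Filter-threshold screening configuration
#'
#' The filter threshold controls how strictly predicted herbs are screened:
#' smaller values are stricter (fewer herbs). Under the default
#' `one_minus_threshold` mapping a herb is kept when its predicted
#' probability is at least `1 - filter_threshold`, so larger thresholds
#' admit more herbs; `direct` keeps herbs with probability at least the
#' threshold itself.
#'
#' @param filter_threshold Value in (0, 1).
#' @param cutoff_mapping `"one_minus_threshold"` or `"direct"`.
#' @return A `herbrx_filter_config` list.
#' @export
filter_config <- function(filter_threshold = 0.2,
                          cutoff_mapping = c("one_minus_threshold", "direct")) {
  if (!(filter_threshold > 0 && filter_threshold < 1)) {
    stop("filter_threshold must be in (0, 1)", call. = FALSE)
  }
  structure(list(filter_threshold = filter_threshold,
                 cutoff_mapping = match.arg(cutoff_mapping)),
            class = "herbrx_filter_config")
}

#' Predict a concrete herb set
#'
#' @param model A trained `herbrx_recommender`.
#' @param features Feature vector (or matrix of rows).
#' @param filter A [filter_config()].
#' @param herb_vocab Herb vocabulary used to name the output.
#' @return Character vector of herb terms (list of vectors for matrix
#'   input); never empty — falls back to the single highest-probability
#'   herb.
#' @export
predict_prescription <- function(model, features, filter = filter_config(),
                                 herb_vocab) {
  X <- if (is.matrix(features)) features else matrix(features, nrow = 1L)
  p <- mlp_forward(model$net, X)$out
  cutoff <- switch(filter$cutoff_mapping,
                   one_minus_threshold = 1 - filter$filter_threshold,
                   direct = filter$filter_threshold)
  herbs <- unclass(herb_vocab)
  out <- lapply(seq_len(nrow(X)), function(i) {
    sel <- which(p[i, ] >= cutoff)
    if (length(sel) == 0L) sel <- which.max(p[i, ])
    herbs[sel]
  })
  if (is.matrix(features)) out else out[[1L]]
}

#' Multi-label recommendation metrics
#'
#' Per-sample precision `|P∩T|/|P|`, recall `|P∩T|/|T|` and IoU
#' `|P∩T|/|P∪T|`, averaged over samples; F1 is the harmonic mean of the
#' averaged precision and recall (per-sample F1 averaging via
#' `per_sample_f1 = TRUE`). The predicted herb count is reported as
#' mean +/- sd.
#'
#' @param predictions,truths Equal-length lists of herb sets (character
#'   vectors); truths non-empty.
#' @param per_sample_f1 Average per-sample F1 instead.
#' @return List: `precision`, `recall`, `f1`, `iou`, `n_herbs_mean`,
#'   `n_herbs_sd`.
#' @export
evaluate_recommendation <- function(predictions, truths,
                                    per_sample_f1 = FALSE) {
  if (length(predictions) != length(truths)) {
    stop("predictions and truths differ in length", call. = FALSE)
  }
  stopifnot(length(predictions) > 0L)
  pr <- vapply(seq_along(predictions), function(i) {
    p <- unique(predictions[[i]]); t <- unique(truths[[i]])
    inter <- length(intersect(p, t))
    c(precision = if (length(p)) inter / length(p) else 0,
      recall = inter / length(t),
      iou = inter / length(union(p, t)),
      n = length(p))
  }, numeric(4))
  P <- mean(pr["precision", ]); R <- mean(pr["recall", ])
  f1 <- if (per_sample_f1) {
    mean(apply(pr, 2L, function(v) {
      if (v["precision"] + v["recall"] == 0) 0 else
        2 * v["precision"] * v["recall"] / (v["precision"] + v["recall"])
    }))
  } else if (P + R == 0) 0 else 2 * P * R / (P + R)
  list(precision = P, recall = R, f1 = f1, iou = mean(pr["iou", ]),
       n_herbs_mean = mean(pr["n", ]),
       n_herbs_sd = stats::sd(pr["n", ]))
}

# visit-level supervised samples for the recommender
.recommender_samples <- function(cohort, cluster_model, spec,
                                 scramble_scheme = FALSE) {
  visits <- all_visits(cohort)
  hpcs <- if (spec$input_mode == "symptom_plus_scheme") {
    # held-out prescriptions are routinely unseen; nearest-centroid silently
    h <- vapply(visits, function(v)
      assign_cluster(cluster_model, v$herbs, quiet = TRUE), integer(1))
    if (scramble_scheme) h <- sample.int(spec$n_clusters, length(h),
                                         replace = TRUE)
    h
  } else {
    rep(NA_integer_, length(visits))
  }
  X <- do.call(rbind, lapply(seq_along(visits), function(i) {
    build_features(visits[[i]],
                   if (is.na(hpcs[i])) NULL else hpcs[i],
                   cohort$symptom_vocab, spec)
  }))
  Y <- do.call(rbind, lapply(visits, function(v)
    encode_state(v$herbs, cohort$herb_vocab)))
  truths <- lapply(visits, `[[`, "herbs")
  list(X = X, Y = Y, truths = truths)
}

#' Symptom-only versus symptom-plus-scheme recommendation experiment
#'
#' Trains a symptom-only recommender and a symptom-plus-scheme recommender
#' on the train split and evaluates both on the test split across a filter
#' threshold grid, reporting per-threshold metrics and the relative
#' improvement of the scheme-augmented model. With
#' `hpc_source = "recorded"`, the scheme input is the cluster of the
#' recorded prescription (the degradation-experiment setting);
#' `"scrambled"` replaces it with random clusters (ablation control).
#'
#' @param cohort A `herbrx_cohort` (all visits are used as samples; the
#'   split is at patient level).
#' @param cluster_model A fitted `herbrx_clusters` model.
#' @param thresholds Filter threshold grid (default `c(0.1, 0.2, 0.3, 0.4)`).
#' @param hpc_source `"recorded"` or `"scrambled"`.
#' @param train_fraction Patient-level train share.
#' @param hidden_sizes,epochs,learning_rate Passed to the recommender.
#' @param seed Integer seed for split, training and scrambling.
#' @return Data frame: `input_mode`, `filter_threshold`, `n_herbs_mean`,
#'   `n_herbs_sd`, `precision`, `recall`, `f1`, `iou`, plus
#'   `*_improvement_pct` columns on the scheme rows.
#' @export
run_recommendation_experiment <- function(cohort, cluster_model,
                                          thresholds = c(0.1, 0.2, 0.3, 0.4),
                                          hpc_source = c("recorded", "scrambled"),
                                          train_fraction = 0.8,
                                          hidden_sizes = c(256L, 128L),
                                          epochs = 60L, learning_rate = 0.01,
                                          seed = 1L) {
  hpc_source <- match.arg(hpc_source)
  split <- split_cohort(cohort, train_fraction, seed = seed)
  n_sym <- length(cohort$symptom_vocab)
  n_herb <- length(cohort$herb_vocab)
  spec_sym <- recommender_spec("symptom", n_sym, n_herb,
                               hidden_sizes = hidden_sizes)
  spec_sch <- recommender_spec("symptom_plus_scheme", n_sym, n_herb,
                               n_clusters = cluster_model$k,
                               hidden_sizes = hidden_sizes)
  scramble <- hpc_source == "scrambled"
  tr_sym <- .recommender_samples(split$train, cluster_model, spec_sym)
  te_sym <- .recommender_samples(split$test, cluster_model, spec_sym)
  tr_sch <- withr::with_seed(seed + 1L,
    .recommender_samples(split$train, cluster_model, spec_sch, scramble))
  te_sch <- withr::with_seed(seed + 2L,
    .recommender_samples(split$test, cluster_model, spec_sch, scramble))
  m_sym <- train_recommender(tr_sym$X, tr_sym$Y, spec_sym, epochs,
                             learning_rate, seed = seed + 3L)
  m_sch <- train_recommender(tr_sch$X, tr_sch$Y, spec_sch, epochs,
                             learning_rate, seed = seed + 3L)
  eval_at <- function(model, te, thr) {
    preds <- predict_prescription(model, te$X, filter_config(thr),
                                  cohort$herb_vocab)
    evaluate_recommendation(preds, te$truths)
  }
  rows <- list()
  for (thr in thresholds) {
    a <- eval_at(m_sym, te_sym, thr)
    b <- eval_at(m_sch, te_sch, thr)
    rows[[length(rows) + 1L]] <- data.frame(
      input_mode = c("symptom", "symptom_plus_scheme"),
      filter_threshold = thr,
      n_herbs_mean = c(a$n_herbs_mean, b$n_herbs_mean),
      n_herbs_sd = c(a$n_herbs_sd, b$n_herbs_sd),
      precision = c(a$precision, b$precision),
      recall = c(a$recall, b$recall),
      f1 = c(a$f1, b$f1),
      iou = c(a$iou, b$iou),
      precision_improvement_pct = c(NA, improvement_rate(b$precision, a$precision)),
      recall_improvement_pct = c(NA, improvement_rate(b$recall, a$recall)),
      f1_improvement_pct = c(NA, improvement_rate(b$f1, a$f1)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
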