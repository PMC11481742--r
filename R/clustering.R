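#' Distinct-prescription feature matrix
#'
#' Prescriptions are deduplicated to distinct herb sets; each distinct set is
#' one row of a binary herb-membership matrix, with a multiplicity count of
#' how many visit records carry it. Clustering operates on distinct rows
#' weighted by multiplicity.
#'
#' @param cohort A `herbrx_cohort`.
#' @return A `herbrx_rx_matrix`: list with `x` (binary matrix, rows =
#'   distinct prescriptions in first-appearance order, columns = herb
#'   vocabulary), `multiplicity`, `keys` (canonical sorted-index keys) and
#'   `herb_vocab`.
#' @export
build_prescription_matrix <- function(cohort) {
  visits <- all_visits(cohort)
  if (length(visits) == 0L) stop("cohort has no visits", call. = FALSE)
  H <- length(cohort$herb_vocab)
  idx_sets <- lapply(visits, function(v)
    sort(vocab_index(cohort$herb_vocab, v$herbs)))
  keys <- vapply(idx_sets, paste, character(1), collapse = ",")
  first <- !duplicated(keys)
  ukeys <- keys[first]
  x <- matrix(0, nrow = length(ukeys), ncol = H,
              dimnames = list(NULL, unclass(cohort$herb_vocab)))
  usets <- idx_sets[first]
  for (i in seq_along(usets)) x[i, usets[[i]]] <- 1
  structure(list(x = x,
                 multiplicity = as.integer(table(factor(keys, levels = ukeys))),
                 keys = ukeys,
                 herb_vocab = cohort$herb_vocab),
            class = "herbrx_rx_matrix")
}

#' @export
print.herbrx_rx_matrix <- function(x, ...) {
  cat(sprintf("<prescription matrix: %d distinct prescriptions (%d records), %d herbs>\n",
              nrow(x$x), sum(x$multiplicity), ncol(x$x)))
  invisible(x)
}

# squared Euclidean distances between rows of x and rows of centers
.dist2 <- function(x, centers) {
  outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * tcrossprod(x, centers)
}

# k-means++ seeding with observation weights
.kmeanspp <- function(x, w, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  first <- sample.int(n, 1L, prob = w)
  centers[1L, ] <- x[first, ]
  d2 <- .dist2(x, centers[1L, , drop = FALSE])[, 1L]
  if (k > 1L) {
    for (j in 2:k) {
      p <- pmax(d2, 0) * w
      nxt <- if (sum(p) <= 0) sample.int(n, 1L) else sample.int(n, 1L, prob = p)
      centers[j, ] <- x[nxt, ]
      d2 <- pmin(d2, .dist2(x, centers[j, , drop = FALSE])[, 1L])
    }
  }
  centers
}

#' Cluster prescriptions with weighted K-means
#'
#' Lloyd's algorithm on the binary herb-membership rows under the Euclidean
#' objective, with rows weighted by multiplicity, k-means++ seeding, and
#' empty clusters repaired by reseeding on the point farthest from its
#' centroid. Deterministic given `seed`.
#'
#' @param matrix A [build_prescription_matrix()] result.
#' @param k Number of clusters (2 <= k <= number of distinct rows).
#' @param seed Integer seed.
#' @param n_start Number of k-means++ restarts; the best objective wins.
#' @param max_iter Lloyd iteration cap.
#' @param representative_k Size of the per-cluster representative herb set;
#'   default `round()` of the multiplicity-weighted mean prescription size,
#'   so representatives live on the scale of real prescriptions.
#' @return A `herbrx_clusters` model: `k`, `assignment` (1-based, per row),
#'   `centroid` (k x herbs multiplicity-weighted mean profile), `size`
#'   (record-weighted), `representative` (list of herb-term sets), `keys` and
#'   `herb_vocab` for prescription lookup, and `objective`.
#' @export
cluster_prescriptions <- function(matrix, k, seed = 1L, n_start = 5L,
                                  max_iter = 100L, representative_k = NULL) {
  stopifnot(inherits(matrix, "herbrx_rx_matrix"))
  x <- matrix$x
  w <- as.numeric(matrix$multiplicity)
  n <- nrow(x)
  if (k > n) stop("k exceeds the number of distinct prescriptions", call. = FALSE)
  if (k < 1L) stop("k must be positive", call. = FALSE)
  run_once <- function() {
    centers <- .kmeanspp(x, w, k)
    assign_old <- rep(0L, n)
    for (iter in seq_len(max_iter)) {
      d2 <- .dist2(x, centers)
      assignment <- max.col(-d2, ties.method = "first")
      # repair empty clusters: reseed on the farthest point
      repeat {
        sizes <- tabulate(assignment, nbins = k)
        empt <- which(sizes == 0L)
        if (length(empt) == 0L) break
        cur_d2 <- d2[cbind(seq_len(n), assignment)]
        far <- which.max(cur_d2 * w)
        centers[empt[1L], ] <- x[far, ]
        d2[, empt[1L]] <- .dist2(x, centers[empt[1L], , drop = FALSE])[, 1L]
        assignment[far] <- empt[1L]
      }
      if (identical(assignment, assign_old)) break
      assign_old <- assignment
      for (j in seq_len(k)) {
        m <- assignment == j
        centers[j, ] <- colSums(x[m, , drop = FALSE] * w[m]) / sum(w[m])
      }
    }
    d2 <- .dist2(x, centers)
    obj <- sum(w * pmax(d2[cbind(seq_len(n), assignment)], 0))
    list(assignment = assignment, centers = centers, objective = obj)
  }
  best <- withr::with_seed(seed, {
    fits <- lapply(seq_len(n_start), function(s) run_once())
    fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
  })
  if (is.null(representative_k)) {
    representative_k <- max(1L, round(sum(rowSums(x) * w) / sum(w)))
  }
  model <- structure(
    list(k = as.integer(k),
         assignment = best$assignment,
         centroid = best$centers,
         size = as.numeric(vapply(seq_len(k), function(j)
           sum(w[best$assignment == j]), numeric(1))),
         representative_k = as.integer(representative_k),
         keys = matrix$keys,
         herb_vocab = matrix$herb_vocab,
         objective = best$objective),
    class = "herbrx_clusters")
  model$representative <- lapply(seq_len(k), function(j)
    cluster_representative(model, j, "top_k", representative_k))
  model
}

#' @export
print.herbrx_clusters <- function(x, ...) {
  cat(sprintf("<prescription clusters: k = %d, objective = %.2f>\n",
              x$k, x$objective))
  invisible(x)
}

#' Representative herb set of a cluster
#'
#' Actions are cluster ids, but the reward's Jaccard risk term compares herb
#' sets; the representative set is the concrete prescription standing in for
#' a cluster.
#'
#' @param model A `herbrx_clusters` model.
#' @param cluster_id Cluster (1-based).
#' @param method `"top_k"` (the `parameter` highest-frequency herbs of the
#'   centroid, ties by herb index) or `"frequency_threshold"` (herbs with
#'   within-cluster frequency >= `parameter`).
#' @param parameter Method parameter; defaults to the model's
#'   `representative_k` for `top_k` and 0.5 for `frequency_threshold`.
#' @return Character vector of herb terms; never empty (falls back to the
#'   single most frequent herb).
#' @export
cluster_representative <- function(model, cluster_id,
                                   method = c("top_k", "frequency_threshold"),
                                   parameter = NULL) {
  method <- match.arg(method)
  stopifnot(cluster_id >= 1L, cluster_id <= model$k)
  freq <- model$centroid[cluster_id, ]
  herbs <- unclass(model$herb_vocab)
  sel <- switch(method,
    top_k = {
      kk <- if (is.null(parameter)) model$representative_k else as.integer(parameter)
      kk <- max(1L, min(kk, length(freq)))
      ord <- order(-freq, seq_along(freq))
      ord[seq_len(kk)][freq[ord[seq_len(kk)]] > 0]
    },
    frequency_threshold = {
      thr <- if (is.null(parameter)) 0.5 else parameter
      which(freq >= thr)
    })
  if (length(sel) == 0L) sel <- which.max(freq)
  herbs[sort(sel)]
}

#' Pairwise chi-square difference between clusters
#'
#' For every cluster pair, a 2 x H contingency table of multiplicity-weighted
#' herb occurrence counts is built over the herbs appearing in either
#' cluster; columns whose pair total is zero are dropped, and the chi-square
#' statistic (no continuity correction) with `H' - 1` degrees of freedom
#' yields `-log10 P`, computed on the log scale (so it does not underflow)
#' and clipped at 300.
#'
#' @param model A `herbrx_clusters` model fitted on `matrix`.
#' @param matrix The [build_prescription_matrix()] the model was fitted on.
#' @param clip Upper clip for `-log10 P` (default 300).
#' @return A `k x k` symmetric matrix of clipped `-log10 P` values, zero
#'   diagonal.
#' @export
pairwise_cluster_difference <- function(model, matrix, clip = 300) {
  stopifnot(inherits(model, "herbrx_clusters"),
            inherits(matrix, "herbrx_rx_matrix"))
  if (length(model$assignment) != nrow(matrix$x)) {
    stop("model was not fitted on this prescription matrix", call. = FALSE)
  }
  k <- model$k
  w <- as.numeric(matrix$multiplicity)
  counts <- vapply(seq_len(k), function(j) {
    m <- model$assignment == j
    colSums(matrix$x[m, , drop = FALSE] * w[m])
  }, numeric(ncol(matrix$x)))  # herbs x k
  out <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      tab <- rbind(counts[, i], counts[, j])
      tab <- tab[, colSums(tab) > 0, drop = FALSE]
      if (ncol(tab) < 2L) {
        warning(sprintf("degenerate 1-column table for clusters %d/%d; difference set to 0",
                        i, j))
        next
      }
      e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      stat <- sum((tab - e)^2 / e)
      df <- ncol(tab) - 1L
      mlog10p <- -stats::pchisq(stat, df, lower.tail = FALSE, log.p = TRUE) / log(10)
      out[i, j] <- out[j, i] <- min(mlog10p, clip)
    }
  }
  out
}

#' Choose the number of prescription clusters
#'
#' Fits K-means at every `k` in `k_grid` and scores each fit by the mean
#' off-diagonal clipped `-log10 P` of [pairwise_cluster_difference()]: larger
#' mean difference means more mutually distinct (more personalised) clusters.
#' Ties — which occur when separation saturates the clip at several `k` —
#' are broken toward the larger `k`, preferring the finer action space at
#' equal statistical separation.
#'
#' @param matrix A [build_prescription_matrix()] result.
#' @param k_grid Integer vector of candidate cluster counts.
#' @param seed Integer seed (each `k` gets a derived sub-seed).
#' @param ... Passed to [cluster_prescriptions()].
#' @return List: `best_k`, `summary` (data frame with `k`,
#'   `mean_neglog10p`, `sd_neglog10p`), and `models` (per-k fitted models,
#'   named by `k`).
#' @export
select_cluster_number <- function(matrix, k_grid, seed = 1L, ...) {
  stopifnot(length(k_grid) > 0L)
  k_grid <- as.integer(k_grid)
  fits <- lapply(seq_along(k_grid), function(i) {
    m <- cluster_prescriptions(matrix, k_grid[i], seed = seed + i, ...)
    d <- pairwise_cluster_difference(m, matrix)
    off <- d[upper.tri(d)]
    list(model = m,
         mean = if (length(off)) mean(off) else 0,
         sd = if (length(off) > 1L) stats::sd(off) else 0)
  })
  means <- vapply(fits, `[[`, numeric(1), "mean")
  best <- max(which(means == max(means)))  # ties -> larger k
  list(best_k = k_grid[best],
       summary = data.frame(k = k_grid,
                            mean_neglog10p = means,
                            sd_neglog10p = vapply(fits, `[[`, numeric(1), "sd")),
       models = stats::setNames(lapply(fits, `[[`, "model"), k_grid))
}

#' Cluster id of an arbitrary prescription
#'
#' Looks the herb set up among the distinct prescriptions the model was
#' fitted on; unseen herb sets are assigned to the nearest centroid with a
#' warning.
#'
#' @param model A `herbrx_clusters` model.
#' @param herbs Character vector of herb terms.
#' @param quiet Suppress the unseen-prescription warning.
#' @return Integer cluster id (1-based).
#' @export
assign_cluster <- function(model, herbs, quiet = FALSE) {
  idx <- sort(vocab_index(model$herb_vocab, herbs))
  key <- paste(idx, collapse = ",")
  pos <- match(key, model$keys)
  if (!is.na(pos)) return(model$assignment[pos])
  if (!quiet) warning("unseen prescription; assigning to nearest centroid")
  v <- numeric(length(model$herb_vocab))
  v[idx] <- 1
  which.min(.dist2(matrix(v, 1L), model$centroid)[1L, ])
}

#' Persist / load a cluster model as JSON
#' @param model A `herbrx_clusters` model.
#' @param path File path.
#' @return `path` ([write_cluster_model()]) or the model
#'   ([read_cluster_model()]).
#' @export
write_cluster_model <- function(model, path) {
  payload <- list(k = model$k, assignment = model$assignment,
                  centroid = model$centroid, size = model$size,
                  representative_k = model$representative_k,
                  representative = model$representative,
                  keys = model$keys,
                  herb_vocab = unclass(model$herb_vocab),
                  objective = model$objective)
  writeLines(jsonlite::toJSON(payload, digits = NA), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_cluster_model
#' @export
read_cluster_model <- function(path) {
  p <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                          simplifyMatrix = FALSE)
  p$centroid <- do.call(rbind, p$centroid)
  structure(list(k = as.integer(p$k), assignment = as.integer(p$assignment),
                 centroid = p$centroid, size = p$size,
                 representative_k = as.integer(p$representative_k),
                 keys = p$keys, herb_vocab = vocabulary(p$herb_vocab),
                 objective = p$objective,
                 representative = lapply(p$representative, as.character)),
            class = "herbrx_clusters")
}
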