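test_that("prescription matrix deduplicates herb sets with multiplicities", {
  ch <- mk_cohort(list(
    list(list(symptoms = "a", herbs = c("A", "B")),
         list(symptoms = "b", herbs = c("A", "B")),
         list(symptoms = "c", herbs = c("B", "C")),
         list(symptoms = "d", herbs = "C"))))
  m <- build_prescription_matrix(ch)
  expect_equal(nrow(m$x), 3L)
  expect_equal(m$multiplicity, c(2L, 1L, 1L))
  expect_equal(sum(m$multiplicity), 4L)
  same <- mk_cohort(list(list(list(symptoms = "a", herbs = c("A", "B")),
                              list(symptoms = "b", herbs = c("B", "A")))))
  expect_equal(nrow(build_prescription_matrix(same)$x), 1L)  # order-free sets
  # row count equals brute-force distinct herb-set count on generated data
  g <- generate_cohort(generator_config(n_patients = 10L, seed = 4L))
  m2 <- build_prescription_matrix(g$cohort)
  brute <- unique(lapply(all_visits(g$cohort), function(v) sort(v$herbs)))
  expect_equal(nrow(m2$x), length(brute))
})

test_that("weighted K-means recovers planted templates and is deterministic", {
  g <- generate_cohort(generator_config(
    n_patients = 80L, n_syndromes = 2L, doctor_skill = 1,
    background_propensity = 0.005, seed = 21L))
  m <- build_prescription_matrix(g$cohort)
  fit <- cluster_prescriptions(m, 2L, seed = 1L)
  # planted label of each distinct prescription = syndrome of the patient it
  # came from (doctor_skill 1 makes every prescription matched)
  syn_of <- stats::setNames(g$truth$syndrome, g$truth$patient_id)
  key_syn <- new.env()
  for (p in g$cohort$patients) {
    for (v in p$visits) {
      key <- paste(sort(match(v$herbs, unclass(g$cohort$herb_vocab))),
                   collapse = ",")
      if (is.null(key_syn[[key]])) key_syn[[key]] <- syn_of[[p$patient_id]]
    }
  }
  planted <- vapply(m$keys, function(k) key_syn[[k]], numeric(1))
  agreement <- max(mean(fit$assignment == planted),
                   mean(fit$assignment == 3L - planted))
  expect_equal(agreement, 1)
  expect_identical(cluster_prescriptions(m, 2L, seed = 1L)$assignment,
                   fit$assignment)
  # saturation: k = number of rows -> zero objective
  small <- build_prescription_matrix(mk_cohort(list(list(
    list(symptoms = "a", herbs = "A"), list(symptoms = "b", herbs = "B"),
    list(symptoms = "c", herbs = "C")))))
  expect_equal(cluster_prescriptions(small, 3L, seed = 1L)$objective, 0)
  expect_error(cluster_prescriptions(small, 5L, seed = 1L), "exceeds")
  # objective is competitive with stats::kmeans on unit-multiplicity data
  ref <- stats::kmeans(m$x[, ], centers = 2L, nstart = 5L)
  expect_lt(fit$objective, ref$tot.withinss * 1.05 + 1e-9)
})

test_that("pairwise chi-square differences match the textbook computation", {
  # identical herb profiles -> statistic 0, p = 1, entry 0
  same <- mk_onehot_matrix(rbind(c(10, 10, 10, 0), c(10, 10, 10, 0)))
  d0 <- pairwise_cluster_difference(same$model, same$matrix)
  expect_equal(d0[1, 2], 0)
  # disjoint herb usage on four herbs, counts (10,10) vs (10,10)
  disj <- mk_onehot_matrix(rbind(c(10, 10, 0, 0), c(0, 0, 10, 10)))
  d1 <- pairwise_cluster_difference(disj$model, disj$matrix)
  tab <- rbind(c(10, 10, 0, 0), c(0, 0, 10, 10))
  expect_equal(d1[1, 2], oracle_chisq_neglog10p(tab), tolerance = 1e-10)
  # symmetry and non-negativity on planted data
  g <- generate_cohort(generator_config(n_patients = 60L, seed = 8L))
  m <- build_prescription_matrix(g$cohort)
  fit <- cluster_prescriptions(m, 3L, seed = 2L)
  d <- pairwise_cluster_difference(fit, m)
  expect_equal(d, t(d))
  expect_true(all(d >= 0))
  expect_true(all(diag(d) == 0))
  # planted clusters are more different than label-permuted ones
  perm <- mk_fake_clusters(withr::with_seed(5L, sample(fit$assignment)), 3L)
  d_perm <- pairwise_cluster_difference(perm, m)
  expect_gt(mean(d[upper.tri(d)]), mean(d_perm[upper.tri(d_perm)]))
  # degenerate single-column table warns and scores 0
  degen <- mk_onehot_matrix(rbind(c(5, 0), c(3, 0)))
  expect_warning(dd <- pairwise_cluster_difference(degen$model, degen$matrix),
                 "degenerate")
  expect_equal(dd[1, 2], 0)
})

test_that("representative herb sets follow the top-k and threshold rules", {
  ch <- mk_cohort(list(list(list(symptoms = "a", herbs = c("A", "B")))))
  m <- build_prescription_matrix(ch)
  fit <- cluster_prescriptions(m, 1L, seed = 1L)
  expect_setequal(cluster_representative(fit, 1L, "top_k", 5L), c("A", "B"))
  # frequency threshold keeps herbs at or above the cutoff
  fit2 <- fit
  fit2$centroid[1, ] <- 0
  fit2$centroid[1, match(c("A", "B"), unclass(fit2$herb_vocab))] <- c(0.9, 0.6)
  ch3 <- mk_cohort(list(list(list(symptoms = "a", herbs = c("A", "B", "C")))))
  expect_setequal(cluster_representative(fit2, 1L, "frequency_threshold", 0.5),
                  c("A", "B"))
  # on planted single-syndrome data the default representative covers the core
  g <- generate_cohort(generator_config(n_patients = 50L, n_syndromes = 2L,
                                        doctor_skill = 1, seed = 31L))
  m2 <- build_prescription_matrix(g$cohort)
  fit3 <- cluster_prescriptions(m2, 2L, seed = 1L)
  core_terms <- lapply(g$templates$herb_core, function(ix) sprintf("herb%03d", ix))
  rep1 <- cluster_representative(fit3, 1L)
  overlap <- vapply(core_terms, function(core)
    length(intersect(rep1, core)), numeric(1))
  expect_gt(max(overlap) / length(core_terms[[1]]), 0.7)
})

test_that("cluster-number selection reports the per-k summary and handles a unit grid", {
  g <- generate_cohort(generator_config(n_patients = 40L, seed = 12L))
  m <- build_prescription_matrix(g$cohort)
  sel <- select_cluster_number(m, 4L, seed = 1L)
  expect_equal(sel$best_k, 4L)
  expect_named(sel$summary, c("k", "mean_neglog10p", "sd_neglog10p"))
  expect_equal(nrow(sel$summary), 1L)
})

test_that("cluster models survive JSON persistence and classify unseen prescriptions", {
  g <- generate_cohort(generator_config(n_patients = 30L, seed = 13L))
  m <- build_prescription_matrix(g$cohort)
  fit <- cluster_prescriptions(m, 3L, seed = 1L)
  tmp <- tempfile(fileext = ".json")
  write_cluster_model(fit, tmp)
  back <- read_cluster_model(tmp)
  expect_equal(back$assignment, fit$assignment)
  expect_equal(back$centroid, fit$centroid, tolerance = 1e-12)
  expect_equal(back$representative, fit$representative)
  seen <- all_visits(g$cohort)[[1]]$herbs
  expect_equal(assign_cluster(back, seen), assign_cluster(fit, seen))
  expect_warning(cl <- assign_cluster(fit, c("herb001", "herb090")), "unseen")
  expect_true(cl >= 1L && cl <= 3L)
})
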