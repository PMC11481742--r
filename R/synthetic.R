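#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the marginal structure of a longitudinal
#' diabetes-clinic cohort — about half the patients have a single visit, the
#' mean visit count is 3.68, symptom counts per visit are approximately
#' normal with mean 10.386 truncated to 1..40, and herb counts per
#' prescription approximately normal with mean 10.059 — and plants a latent
#' syndrome -> effective-prescription structure so that a learnable
#' treatment signal exists: each patient carries one latent syndrome, each
#' syndrome has a matched herb template, and matched treatment resolves
#' symptoms at a higher per-symptom rate than mismatched treatment.
#'
#' @param n_patients Number of patients.
#' @param n_symptoms,n_herbs Vocabulary sizes.
#' @param n_syndromes Number of latent syndrome classes (>= 2).
#' @param p_single_visit Probability a patient has exactly one visit.
#' @param mean_visits Target mean visit count of the mixture law.
#' @param symptom_count_mean,symptom_count_sd,symptom_count_range Truncated
#'   normal law for per-visit symptom counts.
#' @param herb_count_mean,herb_count_sd Normal law for herbs per
#'   prescription, truncated to `[1, n_herbs]`.
#' @param symptom_core_size,herb_core_size Number of high-propensity terms in
#'   each syndrome's symptom/herb template.
#' @param template_overlap Fraction of each symptom core shared across all
#'   syndromes.
#' @param background_propensity Sampling weight of non-core terms relative to
#'   a core weight of 1.
#' @param p_cure_matched,p_cure_mismatched Per-symptom resolution probability
#'   between visits under matched / mismatched treatment
#'   (`p_cure_matched > p_cure_mismatched`).
#' @param p_relapse Per-visit reappearance probability of an absent
#'   syndrome-core symptom.
#' @param doctor_skill Probability that the recorded prescription is drawn
#'   from the patient's matched template rather than a random other one.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A validated `herbrx_gen_config` list.
#' @export
generator_config <- function(n_patients = 500L,
                             n_symptoms = 60L,
                             n_herbs = 90L,
                             n_syndromes = 3L,
                             p_single_visit = 0.496,
                             mean_visits = 3.68,
                             symptom_count_mean = 10.386,
                             symptom_count_sd = 4.0,
                             symptom_count_range = c(1L, 40L),
                             herb_count_mean = 10.059,
                             herb_count_sd = 4.0,
                             symptom_core_size = 16L,
                             herb_core_size = 12L,
                             template_overlap = 0.2,
                             background_propensity = 0.03,
                             p_cure_matched = 0.30,
                             p_cure_mismatched = 0.10,
                             p_relapse = 0.45,
                             doctor_skill = 0.7,
                             seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_symptoms = as.integer(n_symptoms),
              n_herbs = as.integer(n_herbs),
              n_syndromes = as.integer(n_syndromes),
              p_single_visit = p_single_visit,
              mean_visits = mean_visits,
              symptom_count_mean = symptom_count_mean,
              symptom_count_sd = symptom_count_sd,
              symptom_count_range = as.integer(symptom_count_range),
              herb_count_mean = herb_count_mean,
              herb_count_sd = herb_count_sd,
              symptom_core_size = as.integer(symptom_core_size),
              herb_core_size = as.integer(herb_core_size),
              template_overlap = template_overlap,
              background_propensity = background_propensity,
              p_cure_matched = p_cure_matched,
              p_cure_mismatched = p_cure_mismatched,
              p_relapse = p_relapse,
              doctor_skill = doctor_skill,
              seed = as.integer(seed))
  probs <- c(cfg$p_single_visit, cfg$p_cure_matched, cfg$p_cure_mismatched,
             cfg$p_relapse, cfg$doctor_skill, cfg$template_overlap,
             cfg$background_propensity)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$p_cure_matched <= cfg$p_cure_mismatched) {
    stop("p_cure_matched must exceed p_cure_mismatched", call. = FALSE)
  }
  if (cfg$n_syndromes < 2L) stop("n_syndromes must be >= 2", call. = FALSE)
  if (cfg$n_syndromes > cfg$n_symptoms) {
    stop("n_syndromes cannot exceed n_symptoms", call. = FALSE)
  }
  if (cfg$symptom_count_mean < cfg$symptom_count_range[1] ||
      cfg$symptom_count_mean > cfg$symptom_count_range[2]) {
    stop("symptom_count_mean lies outside symptom_count_range", call. = FALSE)
  }
  if (cfg$mean_visits < 2 - cfg$p_single_visit) {
    stop("mean_visits too small for the visit-count mixture law", call. = FALSE)
  }
  shared <- round(cfg$template_overlap * cfg$symptom_core_size)
  if (shared + cfg$n_syndromes * (cfg$symptom_core_size - shared) > cfg$n_symptoms) {
    stop("symptom vocabulary too small for the requested cores/overlap",
         call. = FALSE)
  }
  if (cfg$n_syndromes * cfg$herb_core_size > cfg$n_herbs) {
    stop("herb vocabulary too small for disjoint herb cores", call. = FALSE)
  }
  class(cfg) <- "herbrx_gen_config"
  cfg
}

#' Build the latent syndrome templates
#'
#' Each syndrome gets a symptom propensity vector (core terms at weight 1, a
#' shared block of `round(template_overlap * symptom_core_size)` core terms
#' common to all syndromes, the rest at `background_propensity`) and a
#' matched herb template (disjoint cores across syndromes).
#'
#' @param config A [generator_config()].
#' @return A `herbrx_templates` list with matrices `symptom_propensity`
#'   (`n_syndromes x n_symptoms`), `herb_propensity`, and index lists
#'   `symptom_core`, `herb_core`.
#' @export
generate_templates <- function(config) {
  stopifnot(inherits(config, "herbrx_gen_config"))
  withr::with_seed(config$seed, {
    ns <- config$n_syndromes
    shared_n <- round(config$template_overlap * config$symptom_core_size)
    own_n <- config$symptom_core_size - shared_n
    shared <- seq_len(shared_n)
    sym_core <- lapply(seq_len(ns), function(j) {
      own <- shared_n + (j - 1L) * own_n + seq_len(own_n)
      sort(c(shared, own))
    })
    herb_core <- lapply(seq_len(ns), function(j) {
      (j - 1L) * config$herb_core_size + seq_len(config$herb_core_size)
    })
    sp <- matrix(config$background_propensity, ns, config$n_symptoms)
    hp <- matrix(config$background_propensity, ns, config$n_herbs)
    for (j in seq_len(ns)) {
      sp[j, sym_core[[j]]] <- 1
      hp[j, herb_core[[j]]] <- 1
    }
    structure(list(symptom_propensity = sp, herb_propensity = hp,
                   symptom_core = sym_core, herb_core = herb_core),
              class = "herbrx_templates")
  })
}

# rejection-sampled rounded normal constrained to [lo, hi]
rtrunc_count <- function(n, mean, sd, lo, hi) {
  out <- integer(n)
  need <- seq_len(n)
  while (length(need) > 0L) {
    x <- as.integer(round(stats::rnorm(length(need), mean, sd)))
    ok <- x >= lo & x <= hi
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

#' One step of the planted symptom dynamics
#'
#' Each present symptom resolves independently with probability
#' `p_cure_matched` (matched treatment) or `p_cure_mismatched`; each absent
#' syndrome-core symptom reappears with probability `p_relapse`. If every
#' symptom would resolve, the lowest-index core symptom is retained, since a
#' visit requires at least one symptom.
#'
#' Uses the current RNG state; seed at the call site for reproducibility.
#'
#' @param current Character vector of current symptom terms (non-empty).
#' @param matched Logical: was the treatment matched to the syndrome?
#' @param core_symptoms Character vector, the syndrome's core symptom terms
#'   in vocabulary order.
#' @param config A [generator_config()].
#' @return Character vector, the next visit's symptom set.
#' @export
simulate_visit_transition <- function(current, matched, core_symptoms, config) {
  stopifnot(length(current) > 0L)
  p_cure <- if (matched) config$p_cure_matched else config$p_cure_mismatched
  keep <- stats::runif(length(current)) >= p_cure
  nxt <- current[keep]
  absent_core <- setdiff(core_symptoms, current)
  if (length(absent_core) > 0L) {
    back <- absent_core[stats::runif(length(absent_core)) < config$p_relapse]
    nxt <- c(nxt, back)
  }
  if (length(nxt) == 0L) nxt <- core_symptoms[1]
  nxt
}

#' Generate a synthetic longitudinal cohort
#'
#' Visit counts follow a mixture of a point mass at 1 (probability
#' `p_single_visit`) and `2 + Poisson(lambda)` with `lambda` solved so the
#' mixture mean equals `mean_visits`. First-visit symptoms are drawn by
#' weighted sampling without replacement from the patient's syndrome
#' propensities at a truncated-normal count; prescriptions are drawn from
#' the matched herb template with probability `doctor_skill`, otherwise from
#' a random other template; follow-up symptom sets evolve by
#' [simulate_visit_transition()].
#'
#' @param config A [generator_config()].
#' @return A list: `cohort` (a `herbrx_cohort`), `truth` (data frame with
#'   `patient_id` and 1-based `syndrome` label), `matched` (list, per patient,
#'   of per-visit logicals: was the recorded prescription matched), and
#'   `templates` (the [generate_templates()] output).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "herbrx_gen_config"))
  templates <- generate_templates(config)
  sym_terms <- sprintf("sym%03d", seq_len(config$n_symptoms))
  herb_terms <- sprintf("herb%03d", seq_len(config$n_herbs))
  lambda <- (config$mean_visits - 1) / (1 - config$p_single_visit) - 1
  withr::with_seed(config$seed + 1L, {
    patients <- vector("list", config$n_patients)
    syndrome <- integer(config$n_patients)
    matched_flags <- vector("list", config$n_patients)
    for (i in seq_len(config$n_patients)) {
      pid <- sprintf("P%05d", i)
      syn <- sample.int(config$n_syndromes, 1L)
      syndrome[i] <- syn
      core_sym <- sym_terms[templates$symptom_core[[syn]]]
      nv <- if (stats::runif(1) < config$p_single_visit) 1L else
        2L + stats::rpois(1L, lambda)
      n_sym0 <- rtrunc_count(1L, config$symptom_count_mean,
                             config$symptom_count_sd,
                             config$symptom_count_range[1],
                             min(config$symptom_count_range[2],
                                 config$n_symptoms))
      current <- sym_terms[sample.int(config$n_symptoms, n_sym0,
                                      prob = templates$symptom_propensity[syn, ])]
      visits <- vector("list", nv)
      matched_v <- logical(nv)
      for (t in seq_len(nv)) {
        if (stats::runif(1) < config$doctor_skill || config$n_syndromes == 1L) {
          tmpl <- syn
        } else {
          others <- setdiff(seq_len(config$n_syndromes), syn)
          tmpl <- if (length(others) == 1L) others else sample(others, 1L)
        }
        matched_v[t] <- tmpl == syn
        n_herb <- rtrunc_count(1L, config$herb_count_mean, config$herb_count_sd,
                               1L, config$n_herbs)
        herbs <- herb_terms[sample.int(config$n_herbs, n_herb,
                                       prob = templates$herb_propensity[tmpl, ])]
        # cap symptoms at the truncation range (transitions can only shrink
        # the set or re-add core terms, so this rarely binds)
        if (length(current) > config$symptom_count_range[2]) {
          current <- current[seq_len(config$symptom_count_range[2])]
        }
        visits[[t]] <- visit_record(pid, t - 1L, current, herbs)
        if (t < nv) {
          current <- simulate_visit_transition(current, matched_v[t],
                                               core_sym, config)
        }
      }
      patients[[i]] <- patient_sequence(pid, visits)
      matched_flags[[i]] <- matched_v
    }
    names(matched_flags) <- vapply(patients, function(p) p$patient_id,
                                   character(1))
    list(cohort = cohort(patients, vocabulary(sym_terms),
                         vocabulary(herb_terms)),
         truth = data.frame(
           patient_id = vapply(patients, function(p) p$patient_id, character(1)),
           syndrome = syndrome, stringsAsFactors = FALSE),
         matched = matched_flags,
         templates = templates)
  })
}

#' Write the generator's ground-truth sidecar
#'
#' Ground truth (latent syndrome labels) is kept out of the cohort files so
#' downstream stages cannot accidentally consume it; it lives in a JSONL
#' sidecar used only by recovery tests and reports.
#'
#' @param generated Output of [generate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(generated, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- vapply(seq_len(nrow(generated$truth)), function(i) {
    pid <- generated$truth$patient_id[i]
    jsonlite::toJSON(list(patient_id = jsonlite::unbox(pid),
                          syndrome = jsonlite::unbox(generated$truth$syndrome[i]),
                          matched = generated$matched[[pid]]))
  }, character(1))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}
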