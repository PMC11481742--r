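#' Benchmark reference tables
#'
#' Reference values from a sequential diabetes-care evaluation of this
#' methodology, shipped with the package: per-policy returns (clinician
#' baseline, feed-forward and recurrent Q-learning) and per-threshold
#' recommendation metrics (symptom-only vs scheme-augmented input). They are
#' used to anchor relative-improvement arithmetic; the underlying clinical
#' cohort is not distributed.
#'
#' @return A data frame ([benchmark_returns()]: policy, ssr, scr, mcr;
#'   [benchmark_recommendation()]: input_mode, filter_threshold, herb-count
#'   mean/sd, precision, recall, f1, iou).
#' @export
benchmark_returns <- function() {
  utils::read.csv(system.file("extdata", "benchmark_returns.csv",
                              package = "herbrx"),
                  stringsAsFactors = FALSE)
}

#' @rdname benchmark_returns
#' @export
benchmark_recommendation <- function() {
  utils::read.csv(system.file("extdata", "benchmark_recommendation.csv",
                              package = "herbrx"),
                  stringsAsFactors = FALSE)
}

#' Relative-improvement arithmetic on the benchmark tables
#'
#' Recomputes, from the benchmark reference tables, the relative
#' improvements of the recurrent agent over the feed-forward agent and of
#' both agents over the clinician baseline, and — at filter threshold 0.2 —
#' of the scheme-augmented recommender over the symptom-only one. Values
#' are rounded to three significant digits, the precision at which such
#' improvements are conventionally reported.
#'
#' @return Named list of percentages.
#' @export
benchmark_improvements <- function() {
  ret <- benchmark_returns()
  rec <- benchmark_recommendation()
  v <- function(p, m) ret[ret$policy == p, m]
  r2 <- rec[rec$filter_threshold == 0.2, ]
  w <- function(mode, m) r2[r2$input_mode == mode, m]
  out <- list(
    drqn_vs_dqn_ssr = improvement_rate(v("drqn", "ssr"), v("dqn", "ssr")),
    drqn_vs_dqn_scr = improvement_rate(v("drqn", "scr"), v("dqn", "scr")),
    drqn_vs_dqn_mcr = improvement_rate(v("drqn", "mcr"), v("dqn", "mcr")),
    dqn_vs_doctor_ssr = improvement_rate(v("dqn", "ssr"), v("doctor", "ssr")),
    drqn_vs_doctor_ssr = improvement_rate(v("drqn", "ssr"), v("doctor", "ssr")),
    dqn_vs_doctor_scr = improvement_rate(v("dqn", "scr"), v("doctor", "scr")),
    drqn_vs_doctor_scr = improvement_rate(v("drqn", "scr"), v("doctor", "scr")),
    dqn_vs_doctor_mcr = improvement_rate(v("dqn", "mcr"), v("doctor", "mcr")),
    drqn_vs_doctor_mcr = improvement_rate(v("drqn", "mcr"), v("doctor", "mcr")),
    scheme_vs_symptom_precision_t02 =
      improvement_rate(w("symptom_plus_scheme", "precision"), w("symptom", "precision")),
    scheme_vs_symptom_recall_t02 =
      improvement_rate(w("symptom_plus_scheme", "recall"), w("symptom", "recall")),
    scheme_vs_symptom_f1_t02 =
      improvement_rate(w("symptom_plus_scheme", "f1"), w("symptom", "f1")))
  lapply(out, signif, digits = 3)
}
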