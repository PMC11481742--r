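#' Build a term vocabulary
#'
#' A vocabulary is an ordered set of distinct terms; the position of a term
#' (1-based in R, exposed as 0-based on disk) defines its coordinate in the
#' binary state/feature encodings used throughout the package.
#'
#' @param terms Character vector of terms, in the order they should be
#'   indexed. Duplicates are removed keeping first appearance.
#' @return An object of class `herbrx_vocab`: a character vector of distinct
#'   terms.
#' @export
vocabulary <- function(terms) {
  terms <- as.character(terms)
  terms <- terms[!duplicated(terms)]
  structure(terms, class = "herbrx_vocab")
}

#' @export
print.herbrx_vocab <- function(x, ...) {
  cat(sprintf("<vocabulary of %d terms>\n", length(x)))
  invisible(x)
}

vocab_index <- function(vocab, terms) {
  idx <- match(terms, vocab)
  if (anyNA(idx)) {
    stop("unknown term(s) not in vocabulary: ",
         paste(terms[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}

#' One clinical encounter
#'
#' @param patient_id Patient identifier (string).
#' @param visit_index Non-negative integer, 0-based chronological order.
#' @param symptoms Character vector (a set) of symptom terms; non-empty.
#' @param herbs Character vector (a set) of herb terms; the prescription.
#' @return A `herbrx_visit` object.
#' @export
visit_record <- function(patient_id, visit_index, symptoms, herbs) {
  symptoms <- as.character(symptoms)
  herbs <- as.character(herbs)
  if (length(symptoms) == 0L) {
    stop(sprintf("visit %s/%s has an empty symptom set", patient_id, visit_index),
         call. = FALSE)
  }
  if (length(herbs) == 0L) {
    stop(sprintf("visit %s/%s has an empty herb set", patient_id, visit_index),
         call. = FALSE)
  }
  if (anyDuplicated(symptoms)) {
    stop(sprintf("visit %s/%s has duplicate symptom terms", patient_id, visit_index),
         call. = FALSE)
  }
  if (anyDuplicated(herbs)) {
    stop(sprintf("visit %s/%s has duplicate herb terms", patient_id, visit_index),
         call. = FALSE)
  }
  structure(
    list(patient_id = as.character(patient_id),
         visit_index = as.integer(visit_index),
         symptoms = symptoms, herbs = herbs),
    class = "herbrx_visit")
}

#' A patient's chronologically ordered visit sequence
#'
#' @param patient_id Patient identifier.
#' @param visits List of [visit_record()] objects; they are re-sorted by
#'   `visit_index` and re-indexed 0..(n-1).
#' @return A `herbrx_patient` object.
#' @export
patient_sequence <- function(patient_id, visits) {
  if (length(visits) == 0L) stop("patient has no visits", call. = FALSE)
  ord <- order(vapply(visits, function(v) v$visit_index, integer(1)))
  visits <- visits[ord]
  for (i in seq_along(visits)) {
    if (visits[[i]]$patient_id != patient_id) {
      stop("visit patient_id does not match sequence patient_id", call. = FALSE)
    }
    visits[[i]]$visit_index <- i - 1L
  }
  structure(list(patient_id = as.character(patient_id), visits = visits),
            class = "herbrx_patient")
}

#' Assemble a cohort
#'
#' @param patients List of [patient_sequence()] objects with unique ids.
#' @param symptom_vocab,herb_vocab Vocabularies; if `NULL`, built from the
#'   records in first-appearance order (patients, then visits).
#' @return A `herbrx_cohort` object with fields `patients`, `symptom_vocab`,
#'   `herb_vocab`.
#' @export
cohort <- function(patients, symptom_vocab = NULL, herb_vocab = NULL) {
  ids <- vapply(patients, function(p) p$patient_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate patient ids in cohort", call. = FALSE)
  all_sym <- unlist(lapply(patients, function(p)
    unlist(lapply(p$visits, function(v) v$symptoms))))
  all_herb <- unlist(lapply(patients, function(p)
    unlist(lapply(p$visits, function(v) v$herbs))))
  if (is.null(symptom_vocab)) symptom_vocab <- vocabulary(all_sym)
  if (is.null(herb_vocab)) herb_vocab <- vocabulary(all_herb)
  if (length(patients) > 0L) {
    if (anyNA(match(unique(all_sym), symptom_vocab))) {
      stop("cohort contains symptom terms missing from the symptom vocabulary",
           call. = FALSE)
    }
    if (anyNA(match(unique(all_herb), herb_vocab))) {
      stop("cohort contains herb terms missing from the herb vocabulary",
           call. = FALSE)
    }
  }
  structure(list(patients = patients,
                 symptom_vocab = symptom_vocab,
                 herb_vocab = herb_vocab),
            class = "herbrx_cohort")
}

#' @export
print.herbrx_cohort <- function(x, ...) {
  nv <- sum(vapply(x$patients, function(p) length(p$visits), integer(1)))
  cat(sprintf("<cohort: %d patients, %d visits, %d symptoms, %d herbs>\n",
              length(x$patients), nv, length(x$symptom_vocab),
              length(x$herb_vocab)))
  invisible(x)
}

#' Number of visits per patient
#' @param cohort A `herbrx_cohort`.
#' @return Integer vector named by patient id.
#' @export
visit_counts <- function(cohort) {
  n <- vapply(cohort$patients, function(p) length(p$visits), integer(1))
  names(n) <- vapply(cohort$patients, function(p) p$patient_id, character(1))
  n
}

#' All visit records of a cohort as a flat list
#' @param cohort A `herbrx_cohort`.
#' @return List of `herbrx_visit` objects.
#' @export
all_visits <- function(cohort) {
  unlist(lapply(cohort$patients, function(p) p$visits), recursive = FALSE)
}

# ---- readers / writers ------------------------------------------------------

#' Read a cohort from disk
#'
#' Two plain-text layouts are supported: JSON-lines (one visit object per
#' line with `patient_id`, `visit_index`, `symptoms`, `herbs`) and a long CSV
#' (one row per visit, term lists `";"`-joined). Vocabularies are built from
#' observed terms in first-appearance order; visits are sorted by visit index
#' within patient, patients by first appearance.
#'
#' @param path File path.
#' @param format `"jsonl"` or `"long_csv"`.
#' @return A `herbrx_cohort`.
#' @export
read_cohort <- function(path, format = c("jsonl", "long_csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  rows <- switch(format,
    jsonl = {
      lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      lapply(seq_along(lines), function(i) {
        rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                        error = function(e) stop(sprintf(
                          "parse error at line %d of %s: %s", i, path,
                          conditionMessage(e)), call. = FALSE))
        for (f in c("patient_id", "visit_index", "symptoms", "herbs")) {
          if (is.null(rec[[f]])) {
            stop(sprintf("line %d of %s: missing field '%s'", i, path, f),
                 call. = FALSE)
          }
        }
        rec
      })
    },
    long_csv = {
      df <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = "character", encoding = "UTF-8")
      need <- c("patient_id", "visit_index", "symptoms", "herbs")
      if (!all(need %in% names(df))) {
        stop("long CSV must have columns ", paste(need, collapse = ", "),
             call. = FALSE)
      }
      lapply(seq_len(nrow(df)), function(i) {
        list(patient_id = df$patient_id[i],
             visit_index = as.integer(df$visit_index[i]),
             symptoms = strsplit(df$symptoms[i], ";", fixed = TRUE)[[1]],
             herbs = strsplit(df$herbs[i], ";", fixed = TRUE)[[1]])
      })
    })
  if (length(rows) == 0L) return(cohort(list()))
  pid <- vapply(rows, function(r) as.character(r$patient_id), character(1))
  visits <- lapply(rows, function(r) {
    visit_record(r$patient_id, r$visit_index,
                 unlist(r$symptoms), unlist(r$herbs))
  })
  patients <- lapply(unique(pid), function(id) {
    patient_sequence(id, visits[pid == id])
  })
  cohort(patients)
}

#' Write a cohort to disk
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(c))` reproduces the
#' cohort term-for-term.
#'
#' @param cohort A `herbrx_cohort`.
#' @param path Output file path.
#' @param format `"jsonl"` or `"long_csv"`.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, format = c("jsonl", "long_csv")) {
  format <- match.arg(format)
  visits <- all_visits(cohort)
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop("cannot write to ", path, call. = FALSE))
  on.exit(close(con))
  if (format == "jsonl") {
    lines <- vapply(visits, function(v) {
      jsonlite::toJSON(list(patient_id = jsonlite::unbox(v$patient_id),
                            visit_index = jsonlite::unbox(v$visit_index),
                            symptoms = v$symptoms, herbs = v$herbs))
    }, character(1))
    writeLines(lines, con, useBytes = TRUE)
  } else {
    df <- data.frame(
      patient_id = vapply(visits, function(v) v$patient_id, character(1)),
      visit_index = vapply(visits, function(v) v$visit_index, integer(1)),
      symptoms = vapply(visits, function(v) paste(v$symptoms, collapse = ";"),
                        character(1)),
      herbs = vapply(visits, function(v) paste(v$herbs, collapse = ";"),
                     character(1)),
      stringsAsFactors = FALSE)
    utils::write.csv(df, con, row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read / write a vocabulary file (one term per line; line i = index i-1)
#' @param path File path.
#' @return [read_vocabulary()]: a `herbrx_vocab`.
#' @export
read_vocabulary <- function(path) {
  vocabulary(readLines(path, encoding = "UTF-8", warn = FALSE))
}

#' @rdname read_vocabulary
#' @param vocab A `herbrx_vocab`.
#' @export
write_vocabulary <- function(vocab, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(unclass(vocab), con, useBytes = TRUE)
  invisible(path)
}

# ---- encodings and cohort surgery ------------------------------------------

#' Encode a visit's symptoms as a binary state vector
#'
#' The patient state is the binary indicator vector of the symptom
#' vocabulary: present symptoms are 1, absent symptoms 0.
#'
#' @param record A `herbrx_visit` (or any object with a `$symptoms` field /
#'   a plain character vector of symptom terms).
#' @param vocab The symptom vocabulary.
#' @return Numeric 0/1 vector of length `length(vocab)`.
#' @export
encode_state <- function(record, vocab) {
  symptoms <- if (is.character(record)) record else record$symptoms
  v <- numeric(length(vocab))
  v[vocab_index(vocab, symptoms)] <- 1
  v
}

#' Decode a state vector back to its symptom terms
#' @param state Binary state vector.
#' @param vocab The symptom vocabulary.
#' @return Character vector of present symptom terms.
#' @export
decode_state <- function(state, vocab) {
  unclass(vocab)[state != 0]
}

#' Keep only patients with at least two visits
#'
#' Sequential modelling needs consecutive visit pairs; single-visit patients
#' carry no transition. Vocabularies are left unchanged so state dimensions
#' are stable.
#'
#' @param cohort A `herbrx_cohort`.
#' @return A `herbrx_cohort` containing the multi-visit patients.
#' @export
filter_multivisit <- function(cohort) {
  keep <- vapply(cohort$patients, function(p) length(p$visits) >= 2L, logical(1))
  cohort(cohort$patients[keep], cohort$symptom_vocab, cohort$herb_vocab)
}

#' Patient-level train/test split
#'
#' @param cohort A `herbrx_cohort` with at least 2 patients.
#' @param train_fraction Proportion in (0, 1); the train set has
#'   `round(train_fraction * n)` patients.
#' @param seed Integer seed; the split is reproducible and leaves the global
#'   RNG untouched.
#' @return List with elements `train` and `test`, both `herbrx_cohort`s
#'   sharing the parent vocabularies.
#' @export
split_cohort <- function(cohort, train_fraction = 0.8, seed = 1L) {
  n <- length(cohort$patients)
  if (n < 2L) stop("need at least 2 patients to split", call. = FALSE)
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  n_train <- round(train_fraction * n)
  n_train <- max(1L, min(n - 1L, as.integer(n_train)))
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  list(
    train = cohort(cohort$patients[sort(idx)], cohort$symptom_vocab,
                   cohort$herb_vocab),
    test = cohort(cohort$patients[setdiff(seq_len(n), sort(idx))],
                  cohort$symptom_vocab, cohort$herb_vocab))
}
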