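# End-to-end orchestration on synthetic data: simulate a training corpus
# (from non-survey patients) and an evaluation corpus + survey, train the
# snippet SVM on ground-truth annotations, classify the survey patients'
# snippets, roll up to patient-level calls inside the survey date window,
# and report agreement with self-report.

#' Hash a configuration object
#'
#' MD5 over the R serialization of the object; recorded in pipeline
#' results so every artifact can name the exact configuration that
#' produced it.
#'
#' @param config Any R object.
#' @return Hex MD5 string.
#' @export
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(serialize(config, NULL, version = 2L), tf)
  unname(tools::md5sum(tf))
}

#' Write observations to CSV
#'
#' The snippet tokens are stored space-joined as \code{snippet_text};
#' because the tokenizer is idempotent under space-joining, reading the
#' file back reconstructs the exact token sequence.
#'
#' @param observations Observations data.frame with a \code{tokens} list
#'   column.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_observations_csv <- function(observations, path) {
  out <- observations[, c("note_id", "patient_id", "note_date",
                          "token_index", "keyword", "category", "label")]
  out$snippet_text <- vapply(observations$tokens, paste, "", collapse = " ")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read observations from CSV
#'
#' @param path Path written by [write_observations_csv()].
#' @return Observations data.frame with the \code{tokens} list column
#'   reconstructed.
#' @export
read_observations_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(note_id = "character",
                                        patient_id = "character",
                                        keyword = "character",
                                        category = "character"))
  out$note_date <- as.Date(out$note_date)
  out$label <- if ("label" %in% names(out)) as.character(out$label) else NA_character_
  out$tokens <- strsplit(out$snippet_text, " ", fixed = TRUE)
  out$snippet_text <- NULL
  out
}

#' Run the full synthetic pipeline
#'
#' Chains simulate, extract, annotate, train, predict, roll-up and
#' evaluate. The SVM is trained on notes from a separate set of generated
#' patients (the survey participants' own notes are never used for
#' training); evaluation notes are restricted to the survey-anchored date
#' window before classification.
#'
#' @param config [generator_config()] for the evaluation (survey) cohort.
#' @param n_train_patients Patients in the disjoint training cohort
#'   (default 150).
#' @param C SVM cost (default 1).
#' @param window Snippet context width (default 20).
#' @param prevalence_threshold Strict prevalence filter for the agreement
#'   summary (default 0.10).
#' @param days_before,days_after Note date window around the survey date
#'   (defaults 365 and 30).
#' @param run_cv Also run k-fold cross-validation on the training
#'   observations (default FALSE).
#' @param k Folds for \code{run_cv} (default 10).
#' @return An object of class \code{supp_pipeline}: list with
#'   \code{model}, \code{cv} (or NULL), \code{calls}, \code{survey},
#'   \code{agreement}, \code{truth_patient_use}, \code{n_observations},
#'   \code{config}, \code{config_hash}.
#' @export
run_pipeline <- function(config = generator_config(),
                         n_train_patients = 150L, C = 1, window = 20L,
                         prevalence_threshold = 0.10,
                         days_before = 365L, days_after = 30L,
                         run_cv = FALSE, k = 10L) {
  stopifnot(inherits(config, "supp_genconfig"))
  lex <- config$lexicon
  train_cfg <- config
  train_cfg$n_patients <- as.integer(n_train_patients)
  train_cfg$patient_prefix <- "T"
  train_cfg$seed <- config$seed + 5000L
  train <- generate_corpus(train_cfg)
  obs_tr <- corpus_observations(train$notes, lex, window)
  obs_tr <- annotate_observations(obs_tr, train$truth_observations)
  model <- snippet_svm(obs_tr, C = C)
  cv <- if (isTRUE(run_cv)) cross_validate(obs_tr, k = k, C = C,
                                           seed = config$seed) else NULL
  ev <- generate_corpus(config)
  survey <- generate_survey(ev$truth_patient_use, config)
  notes_f <- filter_notes(ev$notes, config$survey_date, days_before, days_after)
  obs_ev <- corpus_observations(notes_f, lex, window)
  pred <- predict(model, obs_ev)
  calls <- aggregate_calls(
    data.frame(patient_id = obs_ev$patient_id, category = obs_ev$category,
               pred = pred, stringsAsFactors = FALSE),
    categories = lex$categories,
    patients = sort(unique(survey$patient_id))
  )
  agreement <- agreement_report(calls, survey, prevalence_threshold)
  structure(list(model = model, cv = cv, calls = calls, survey = survey,
                 agreement = agreement,
                 truth_patient_use = ev$truth_patient_use,
                 n_observations = c(train = nrow(obs_tr), eval = nrow(obs_ev)),
                 config = config, config_hash = config_hash(config)),
            class = "supp_pipeline")
}

#' @export
print.supp_pipeline <- function(x, ...) {
  cat("Supplement-use NLP pipeline run (config ", x$config_hash, ")\n", sep = "")
  cat("  training observations: ", x$n_observations[["train"]],
      "; evaluation observations: ", x$n_observations[["eval"]], "\n\n",
      sep = "")
  if (!is.null(x$cv)) {
    print(x$cv)
    cat("\n")
  }
  print(x$agreement)
  invisible(x)
}
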