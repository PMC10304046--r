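# Patient-level roll-up: restrict notes to the survey-anchored window,
# then call a patient positive for a category iff at least one of their
# keyword occurrences in that category is classified positive.

#' Filter notes to the survey-anchored date window
#'
#' Keeps notes dated between \code{days_before} days before and
#' \code{days_after} days after the survey date, both bounds inclusive.
#' Defaults encode "one year prior to one month after" as 365 and 30 days.
#'
#' @param notes Notes data.frame with a \code{note_date} column (Date or
#'   ISO-8601 character).
#' @param survey_date The anchoring survey date (Date or ISO-8601).
#' @param days_before,days_after Window half-widths in days (365, 30).
#' @return The subset of \code{notes} inside the window.
#' @export
filter_notes <- function(notes, survey_date, days_before = 365L,
                         days_after = 30L) {
  stopifnot(is.data.frame(notes), "note_date" %in% names(notes))
  sd <- as.Date(survey_date)
  nd <- as.Date(notes$note_date)
  if (anyNA(sd) || anyNA(nd)) stop("invalid date(s)")
  keep <- nd >= sd - days_before & nd <= sd + days_after
  notes[keep, , drop = FALSE]
}

#' Aggregate per-occurrence predictions to patient-level category calls
#'
#' Any-positive rule: a patient is called an active user of a category iff
#' at least one of their observations in that category was predicted
#' "yes". When a category universe is supplied, categories (and patients)
#' with zero observations appear with \code{nlp_use = FALSE}.
#'
#' @param predictions Data.frame with \code{patient_id}, \code{category}
#'   and \code{pred} ("yes"/"no"), one row per classified observation.
#' @param categories Optional category universe (character); defaults to
#'   the categories present in \code{predictions}.
#' @param patients Optional patient universe; defaults to the patients
#'   present in \code{predictions}.
#' @return Data.frame \code{patient_id}, \code{category}, \code{nlp_use},
#'   \code{n_snippets}, \code{n_positive}, one row per (patient, category).
#' @export
aggregate_calls <- function(predictions, categories = NULL, patients = NULL) {
  stopifnot(is.data.frame(predictions),
            all(c("patient_id", "category", "pred") %in% names(predictions)))
  pr <- tolower(as.character(predictions$pred))
  if (nrow(predictions) && !all(pr %in% c("yes", "no"))) {
    stop("predictions must be 'yes' or 'no'")
  }
  if (is.null(categories)) categories <- sort(unique(predictions$category))
  if (is.null(patients)) patients <- sort(unique(as.character(predictions$patient_id)))
  grid <- expand.grid(category = categories, patient_id = patients,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(grid$patient_id, grid$category, sep = "\r")
  pkey <- paste(predictions$patient_id, predictions$category, sep = "\r")
  n_snip <- as.integer(table(factor(pkey, levels = key)))
  n_pos <- as.integer(table(factor(pkey[pr == "yes"], levels = key)))
  out <- data.frame(patient_id = grid$patient_id, category = grid$category,
                    nlp_use = n_pos >= 1L, n_snippets = n_snip,
                    n_positive = n_pos, stringsAsFactors = FALSE)
  out[order(out$patient_id, out$category), , drop = FALSE]
}
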