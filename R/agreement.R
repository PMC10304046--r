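# Agreement between patient-level NLP calls and survey self-report.
# The survey is treated as the reference standard: precision and recall
# are oriented with survey answers as truth — even though self-report is
# itself imperfect (patients often do not count physician-prescribed
# items such as folic acid or melatonin as "supplements").

#' Confusion counts and metrics for one supplement category
#'
#' Counts over the survey patient universe, survey as reference:
#' tp = NLP and survey both positive, fp = NLP positive only, fn = survey
#' positive only, tn = both negative. A patient with no survey row for the
#' category counts as survey-negative; a patient present in \code{calls}
#' but absent from the survey altogether is a universe mismatch and errors.
#'
#' @param calls Patient-level calls ([aggregate_calls()] output).
#' @param survey Survey data.frame: \code{patient_id}, \code{category},
#'   \code{reported_use} (logical), optionally \code{survey_date}.
#' @param category The category to evaluate.
#' @return One-row data.frame: \code{category}, \code{tp}, \code{fp},
#'   \code{fn}, \code{tn}, \code{precision}, \code{recall}, \code{f1},
#'   \code{prevalence} (fraction of survey patients reporting use).
#'   Undefined ratios are NA.
#' @export
category_confusion <- function(calls, survey, category) {
  stopifnot(is.data.frame(calls), is.data.frame(survey),
            all(c("patient_id", "category", "nlp_use") %in% names(calls)),
            all(c("patient_id", "category", "reported_use") %in% names(survey)))
  patients <- sort(unique(as.character(survey$patient_id)))
  extra <- setdiff(unique(as.character(calls$patient_id)), patients)
  if (length(extra)) {
    stop("universe mismatch: patient(s) in calls but not in survey: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  }
  sv <- survey[survey$category == category, , drop = FALSE]
  if (anyDuplicated(sv$patient_id)) {
    stop("duplicate (patient_id, category) rows in survey for ", category)
  }
  cl <- calls[calls$category == category, , drop = FALSE]
  nlp <- patients %in% cl$patient_id[cl$nlp_use]
  rep <- patients %in% sv$patient_id[as.logical(sv$reported_use)]
  tp <- sum(nlp & rep); fp <- sum(nlp & !rep)
  fn <- sum(!nlp & rep); tn <- sum(!nlp & !rep)
  m <- precision_recall_f1(tp, fp, fn)
  data.frame(category = category, tp = tp, fp = fp, fn = fn, tn = tn,
             precision = m[["precision"]], recall = m[["recall"]],
             f1 = m[["f1"]], prevalence = mean(rep),
             stringsAsFactors = FALSE)
}

.pooled_metrics <- function(per_category) {
  m <- precision_recall_f1(sum(per_category$tp), sum(per_category$fp),
                           sum(per_category$fn))
  as.list(m)
}

#' Macro-average of per-category metrics
#'
#' Unweighted arithmetic means of the precision, recall and F1 columns.
#' The macro F1 is the mean of the per-category F1 values, not the
#' harmonic mean of the macro precision and recall. Categories with
#' undefined (NA) metrics are dropped from the corresponding mean with a
#' warning.
#'
#' @param per_category Data.frame with \code{precision}, \code{recall},
#'   \code{f1} columns (confusion counts are not needed).
#' @return List \code{precision}, \code{recall}, \code{f1}.
#' @export
macro_average <- function(per_category) {
  stopifnot(all(c("precision", "recall", "f1") %in% names(per_category)))
  if (nrow(per_category) == 0L) stop("no categories to average")
  n_na <- sum(is.na(per_category$precision) | is.na(per_category$recall) |
                is.na(per_category$f1))
  if (n_na > 0L) {
    warning(n_na, " categor(ies) with undefined metrics excluded from macro means")
  }
  list(precision = mean(per_category$precision, na.rm = TRUE),
       recall = mean(per_category$recall, na.rm = TRUE),
       f1 = mean(per_category$f1, na.rm = TRUE))
}

#' Agreement report between NLP calls and survey self-report
#'
#' Per-category confusion matrices plus micro and macro summaries, with a
#' prevalence filter: categories reported by a fraction of participants
#' strictly greater than \code{prevalence_threshold} form the "included"
#' set used for the headline micro/macro rows (rare categories have too
#' few positives for stable metrics). Unfiltered summaries over all
#' categories are also reported. Micro metrics pool tp/fp/fn counts;
#' macro metrics are unweighted means ([macro_average()]).
#'
#' @param calls Patient-level calls ([aggregate_calls()] output).
#' @param survey Survey data.frame (\code{patient_id}, \code{category},
#'   \code{reported_use}).
#' @param prevalence_threshold Strict lower bound on prevalence for the
#'   filtered summaries (default 0.10).
#' @param categories Optional category universe; defaults to the union of
#'   categories in \code{calls} and \code{survey}.
#' @return An object of class \code{supp_agreement}: list with
#'   \code{per_category}, \code{included} (category names),
#'   \code{micro}, \code{macro} (filtered), \code{micro_all},
#'   \code{macro_all} (unfiltered), \code{prevalence_threshold},
#'   \code{n_participants}.
#' @export
agreement_report <- function(calls, survey, prevalence_threshold = 0.10,
                             categories = NULL) {
  if (is.null(categories)) {
    categories <- sort(union(unique(calls$category), unique(survey$category)))
  }
  if (length(categories) == 0L) stop("no categories to evaluate")
  per <- do.call(rbind, lapply(categories, function(cat) {
    category_confusion(calls, survey, cat)
  }))
  rownames(per) <- NULL
  included <- per$category[per$prevalence > prevalence_threshold]
  if (length(included) == 0L) {
    stop("no category exceeds the prevalence threshold of ",
         prevalence_threshold)
  }
  inc <- per[per$category %in% included, , drop = FALSE]
  structure(list(per_category = per, included = included,
                 micro = .pooled_metrics(inc),
                 macro = macro_average(inc),
                 micro_all = .pooled_metrics(per),
                 macro_all = suppressWarnings(macro_average(per)),
                 prevalence_threshold = prevalence_threshold,
                 n_participants = length(unique(as.character(survey$patient_id)))),
            class = "supp_agreement")
}

#' @export
print.supp_agreement <- function(x, digits = 2, ...) {
  cat("Agreement of NLP supplement calls with survey self-report\n")
  cat("  participants: ", x$n_participants,
      "; categories reported by >", round(100 * x$prevalence_threshold),
      "% of participants: ", length(x$included), " of ",
      nrow(x$per_category), "\n\n", sep = "")
  inc <- x$per_category[x$per_category$category %in% x$included, ,
                        drop = FALSE]
  tab <- data.frame(category = inc$category,
                    precision = round(inc$precision, digits),
                    recall = round(inc$recall, digits),
                    f1 = round(inc$f1, digits))
  tab <- rbind(tab,
               data.frame(category = "micro-avg",
                          precision = round(x$micro$precision, digits),
                          recall = round(x$micro$recall, digits),
                          f1 = round(x$micro$f1, digits)),
               data.frame(category = "macro-avg",
                          precision = round(x$macro$precision, digits),
                          recall = round(x$macro$recall, digits),
                          f1 = round(x$macro$f1, digits)))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write an agreement report as JSON
#'
#' @param report A \code{supp_agreement}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_agreement_json <- function(report, path) {
  stopifnot(inherits(report, "supp_agreement"))
  payload <- list(format = "supp_agreement", version = 1L,
                  prevalence_threshold = report$prevalence_threshold,
                  n_participants = report$n_participants,
                  included = report$included,
                  per_category = report$per_category,
                  micro = report$micro, macro = report$macro,
                  micro_all = report$micro_all, macro_all = report$macro_all)
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows", na = "null"),
             path, useBytes = TRUE)
  invisible(path)
}
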