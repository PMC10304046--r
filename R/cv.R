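# Stratified k-fold cross-validation with the feature space rebuilt inside
# every training fold, so no test-fold token ever contributes a feature
# column or a weight (no leakage).

#' Precision, recall and F1 from confusion counts
#'
#' Ratios with zero denominators are returned as \code{NA}, never silently
#' coerced to 0.
#'
#' @param tp,fp,fn True positive, false positive, false negative counts.
#' @return Named numeric vector \code{precision}, \code{recall}, \code{f1}.
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  c(precision = precision, recall = recall, f1 = f1)
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall Numeric values in [0, 1].
#' @return The F1 value \code{2pr/(p+r)} (NA when p + r = 0).
#' @export
harmonic_f1 <- function(precision, recall) {
  ifelse(is.na(precision) | is.na(recall) | precision + recall == 0,
         NA_real_, 2 * precision * recall / (precision + recall))
}

#' Stratified fold assignment
#'
#' Observations of each class are shuffled (under \code{seed}) and dealt
#' round-robin into \code{k} folds, so every fold has a near-identical
#' class balance.
#'
#' @param labels Character/factor vector of class labels.
#' @param k Number of folds.
#' @param seed Integer RNG seed.
#' @return Integer vector of fold ids in 1..k, one per observation.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  stopifnot(k >= 2L, length(labels) >= k)
  labels <- as.character(labels)
  fold <- integer(length(labels))
  set.seed(as.integer(seed))
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.class_metrics <- function(truth, pred, cls) {
  tp <- sum(pred == cls & truth == cls)
  fp <- sum(pred == cls & truth != cls)
  fn <- sum(pred != cls & truth == cls)
  m <- precision_recall_f1(tp, fp, fn)
  data.frame(class = cls, support = sum(truth == cls),
             precision = m[["precision"]], recall = m[["recall"]],
             f1 = m[["f1"]], stringsAsFactors = FALSE)
}

#' Stratified k-fold cross-validation of the snippet SVM
#'
#' Inside each fold the bigram/keyword feature space is rebuilt from the
#' training observations only, a fresh SVM is fit, and the held-out fold
#' is predicted. Reported are per-class precision/recall/F1 for "yes" and
#' "no" and their support-weighted averages. Fully deterministic under a
#' fixed seed.
#'
#' @param observations Labeled observations (both classes present).
#' @param k Number of folds (default 10).
#' @param C Soft-margin cost (default 1).
#' @param seed Integer seed controlling the fold shuffle.
#' @return An object of class \code{snippet_cv}: list with
#'   \code{per_class} (rows yes/no), \code{weighted} (support-weighted
#'   averages), \code{fold} (assignment vector), \code{predictions},
#'   \code{fold_weights} (per-fold named weight vectors), \code{k},
#'   \code{C}, \code{seed}.
#' @export
cross_validate <- function(observations, k = 10L, C = 1, seed = 1L) {
  stopifnot(is.data.frame(observations), "label" %in% names(observations))
  n <- nrow(observations)
  if (k > n) stop("k = ", k, " exceeds the number of observations (", n, ")")
  lab <- tolower(as.character(observations$label))
  if (length(unique(lab)) < 2L) {
    stop("degenerate training set: both 'yes' and 'no' labels are required")
  }
  fold <- stratified_folds(lab, k, seed)
  pred <- character(n)
  fold_weights <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(fold != f)
    te <- which(fold == f)
    m <- snippet_svm(observations[tr, , drop = FALSE], C = C)
    fold_weights[[f]] <- m$w
    if (length(te)) {
      pred[te] <- predict(m, observations[te, , drop = FALSE])
    }
  }
  per_class <- rbind(.class_metrics(lab, pred, "yes"),
                     .class_metrics(lab, pred, "no"))
  wts <- per_class$support / sum(per_class$support)
  weighted <- data.frame(
    class = "weighted avg", support = sum(per_class$support),
    precision = sum(wts * per_class$precision),
    recall = sum(wts * per_class$recall),
    f1 = sum(wts * per_class$f1), stringsAsFactors = FALSE
  )
  structure(list(per_class = per_class, weighted = weighted, fold = fold,
                 predictions = data.frame(label = lab, pred = pred,
                                          fold = fold,
                                          stringsAsFactors = FALSE),
                 fold_weights = fold_weights, k = k, C = C, seed = seed),
            class = "snippet_cv")
}

#' @export
print.snippet_cv <- function(x, digits = 3, ...) {
  cat("Snippet SVM, ", x$k, "-fold stratified cross-validation (n = ",
      nrow(x$predictions), ", C = ", format(x$C), ", seed = ", x$seed,
      ")\n\n", sep = "")
  tab <- rbind(x$per_class, x$weighted)
  tab$precision <- round(tab$precision, digits)
  tab$recall <- round(tab$recall, digits)
  tab$f1 <- round(tab$f1, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
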