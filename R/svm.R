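# libsvm hands support vectors back as a SparseM row-compressed matrix
# when the design matrix is sparse; normalise to Matrix's column format.
.as_dgc <- function(sv) {
  if (inherits(sv, "matrix.csr")) {
    n <- sv@dimension[1L]
    Matrix::sparseMatrix(i = rep(seq_len(n), diff(sv@ia)), j = sv@ja,
                         x = sv@ra, dims = sv@dimension)
  } else {
    methods::as(as.matrix(sv), "CsparseMatrix")
  }
}

# Linear soft-margin SVM over snippet features. Fitting goes through
# libsvm (e1071) with a linear kernel; the fitted object keeps only the
# explicit linear decision function (w, b) over the feature columns, so
# prediction and serialization are independent of the solver.

#' Fit a linear SVM classifying keyword occurrences as active use
#'
#' Trains a soft-margin linear support vector machine (hinge loss + L2
#' penalty, cost parameter \code{C}) on labeled snippet observations.
#' Features are binary: the unique bigrams of the training snippets plus a
#' one-hot indicator of the observation's keyword (see
#' [build_feature_space()]). The fit is deterministic given the data and
#' \code{C}. The returned object stores the explicit weight vector and
#' bias; \code{decision(x) = w . x + b}, positive values meaning "yes"
#' (active use).
#'
#' @param observations Labeled observations: a data.frame with a
#'   \code{tokens} list column, a \code{keyword} column and a \code{label}
#'   column with both values "yes" and "no" present.
#' @param C Soft-margin cost (default 1).
#' @param space Optional pre-built \code{supp_feature_space}; by default
#'   built from \code{observations}.
#' @return An object of class \code{snippet_svm} with elements
#'   \code{space}, \code{w}, \code{b}, \code{levels}, \code{C},
#'   \code{n_obs}, \code{n_sv} and \code{call}.
#' @seealso [predict.snippet_svm()], [cross_validate()],
#'   [write_snippet_svm()]
#' @examples
#' obs <- data.frame(keyword = c("melatonin", "niacin"))
#' obs$tokens <- list(c("MELATONIN", "5MG", "ACTIVE", "Give:", "5MG"),
#'                    c("ALLERGIES:", "SULFA", ",", "NIACIN"))
#' obs$label <- c("yes", "no")
#' fit <- snippet_svm(obs)
#' predict(fit, obs)
#' @export
snippet_svm <- function(observations, C = 1, space = NULL) {
  stopifnot(is.data.frame(observations), "label" %in% names(observations),
            is.numeric(C), length(C) == 1L, C > 0)
  lab <- tolower(as.character(observations$label))
  if (anyNA(lab)) stop("all training observations must be labeled")
  if (!all(lab %in% c("yes", "no"))) stop("labels must be 'yes' or 'no'")
  if (length(unique(lab)) < 2L) {
    stop("degenerate training set: both 'yes' and 'no' labels are required")
  }
  if (is.null(space)) space <- build_feature_space(observations)
  x <- vectorize_observations(observations, space)
  y <- factor(lab, levels = c("no", "yes"))
  fit <- e1071::svm(x, y, type = "C-classification", kernel = "linear",
                    cost = C, scale = FALSE)
  w <- as.numeric(Matrix::crossprod(.as_dgc(fit$SV), fit$coefs))
  b <- -fit$rho
  # libsvm orients the decision value toward the first training label it
  # sees; normalise so that positive decision values mean "yes"
  first <- fit$levels[fit$labels[1L]]
  if (!identical(first, "yes")) {
    w <- -w
    b <- -b
  }
  names(w) <- colnames(x)
  structure(list(space = space, w = w, b = b, levels = c("no", "yes"),
                 C = C, n_obs = nrow(observations), n_sv = nrow(fit$SV),
                 call = match.call()),
            class = "snippet_svm")
}

#' Predict active-use labels for snippet observations
#'
#' @param object A \code{snippet_svm}.
#' @param newdata Observations data.frame (with \code{tokens} and
#'   \code{keyword}); bigrams unseen at training are ignored, keywords
#'   unseen at training use the "(unknown)" indicator.
#' @param type \code{"class"} for "yes"/"no" labels, \code{"decision"}
#'   for the raw signed margin \code{w . x + b}.
#' @param ... Unused.
#' @return Character vector of labels, or numeric decision values.
#' @export
predict.snippet_svm <- function(object, newdata, type = c("class", "decision"),
                                ...) {
  type <- match.arg(type)
  x <- vectorize_observations(newdata, object$space)
  d <- as.numeric(x %*% object$w) + object$b
  if (type == "decision") return(d)
  ifelse(d > 0, "yes", "no")
}

#' @export
print.snippet_svm <- function(x, ...) {
  cat("Linear snippet SVM (active supplement use)\n")
  cat("  features: ", length(x$space$bigrams), " bigrams + ",
      length(x$space$keywords), " keyword levels (+1 unknown)\n", sep = "")
  cat("  training observations: ", x$n_obs, "; support vectors: ", x$n_sv,
      "; C = ", format(x$C), "\n", sep = "")
  invisible(x)
}

#' @export
summary.snippet_svm <- function(object, ...) {
  cat("Linear snippet SVM\n")
  print(object)
  nz <- sum(object$w != 0)
  cat("  nonzero weights: ", nz, " of ", length(object$w),
      "; bias: ", format(object$b, digits = 4), "\n", sep = "")
  top <- sort(object$w)
  k <- min(5L, length(top))
  cat("  strongest 'no' features: ",
      paste(names(top)[seq_len(k)], collapse = ", "), "\n", sep = "")
  cat("  strongest 'yes' features: ",
      paste(rev(names(top))[seq_len(k)], collapse = ", "), "\n", sep = "")
  invisible(object)
}

#' @export
coef.snippet_svm <- function(object, ...) {
  c(object$w, "(bias)" = object$b)
}

#' Serialize a fitted snippet SVM to versioned JSON
#'
#' The file stores the feature space and the linear decision function at
#' full double precision, so a read-back model reproduces decision values
#' bit for bit.
#'
#' @param model A \code{snippet_svm}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_snippet_svm <- function(model, path) {
  stopifnot(inherits(model, "snippet_svm"))
  # weights are stored as %.17g strings: 17 significant decimal digits
  # round-trip IEEE doubles exactly
  payload <- list(
    format = "snippet_svm", version = 1L,
    C = model$C, b = sprintf("%.17g", model$b),
    levels = model$levels,
    bigrams = model$space$bigrams,
    keywords = model$space$keywords,
    w = sprintf("%.17g", unname(model$w)),
    n_obs = model$n_obs, n_sv = model$n_sv
  )
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA),
             path, useBytes = TRUE)
  invisible(path)
}

#' Read a serialized snippet SVM
#'
#' @param path Path written by [write_snippet_svm()].
#' @return A \code{snippet_svm}.
#' @export
read_snippet_svm <- function(path) {
  p <- jsonlite::fromJSON(path)
  if (!identical(p$format, "snippet_svm")) stop("not a snippet_svm model file")
  space <- structure(list(bigrams = as.character(p$bigrams),
                          keywords = as.character(p$keywords),
                          n_features = length(p$bigrams) + length(p$keywords) + 1L),
                     class = "supp_feature_space")
  w <- as.numeric(p$w)
  names(w) <- c(space$bigrams, paste0("kw:", space$keywords), "kw:(unknown)")
  structure(list(space = space, w = w, b = as.numeric(p$b),
                 levels = as.character(p$levels), C = as.numeric(p$C),
                 n_obs = as.integer(p$n_obs), n_sv = as.integer(p$n_sv),
                 call = NULL),
            class = "snippet_svm")
}
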