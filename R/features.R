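# Featurization: binary indicators over the unique bigrams of the training
# snippets, plus a one-hot indicator of which lexicon keyword the
# observation classifies. Bigrams unseen at training are ignored at
# inference; unseen keywords route to an explicit "(unknown)" level.

#' Build the bigram + keyword feature space from training observations
#'
#' Bigrams are ordered pairs of adjacent case-folded tokens occurring in
#' any training snippet; the space also carries one keyword-indicator
#' level per distinct training keyword plus a reserved \code{"(unknown)"}
#' level. Column order is lexicographic and deterministic.
#'
#' @param observations Labeled observations (data.frame with a
#'   \code{tokens} list column and a \code{keyword} column).
#' @return An object of class \code{supp_feature_space}: list with
#'   \code{bigrams} (sorted character vector, tokens joined by a space),
#'   \code{keywords} (sorted character vector) and \code{n_features}.
#' @export
build_feature_space <- function(observations) {
  stopifnot(is.data.frame(observations), "tokens" %in% names(observations))
  if (nrow(observations) == 0L) stop("cannot build a feature space from zero observations")
  bg <- unique(unlist(lapply(observations$tokens, .snippet_bigrams),
                      use.names = FALSE))
  bg <- sort(bg, method = "radix")
  kw <- sort(unique(tolower(observations$keyword)), method = "radix")
  structure(list(bigrams = bg, keywords = kw,
                 n_features = length(bg) + length(kw) + 1L),
            class = "supp_feature_space")
}

#' @export
print.supp_feature_space <- function(x, ...) {
  cat("Feature space: ", length(x$bigrams), " bigram features + ",
      length(x$keywords), " keyword levels (+1 unknown)\n", sep = "")
  invisible(x)
}

.snippet_bigrams <- function(tokens) {
  n <- length(tokens)
  if (n < 2L) return(character())
  t <- tolower(tokens)
  paste(t[-n], t[-1L])
}

#' Vectorize observations into a sparse design matrix
#'
#' Binary presence indicators: one column per known bigram (set when the
#' bigram occurs in the observation's snippet) and a one-hot block for the
#' observation's keyword. Two observations on the same snippet with
#' different keywords share bigram bits and differ only in the keyword
#' block.
#'
#' @param observations Observations data.frame (with \code{tokens} and
#'   \code{keyword}).
#' @param space A \code{supp_feature_space}.
#' @return A \code{dgCMatrix} with \code{nrow(observations)} rows and
#'   \code{space$n_features} columns, with column names.
#' @export
vectorize_observations <- function(observations, space) {
  stopifnot(inherits(space, "supp_feature_space"))
  n <- nrow(observations)
  nb <- length(space$bigrams)
  nk <- length(space$keywords)
  ii <- vector("list", n)
  jj <- vector("list", n)
  for (i in seq_len(n)) {
    bg <- unique(.snippet_bigrams(observations$tokens[[i]]))
    col <- match(bg, space$bigrams)
    col <- col[!is.na(col)]
    k <- match(tolower(observations$keyword[[i]]), space$keywords)
    kcol <- nb + (if (is.na(k)) nk + 1L else k)
    jj[[i]] <- c(col, kcol)
    ii[[i]] <- rep.int(i, length(col) + 1L)
  }
  m <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = 1,
    dims = c(n, space$n_features),
    dimnames = list(NULL, c(space$bigrams,
                            paste0("kw:", space$keywords), "kw:(unknown)"))
  )
  methods::as(m, "CsparseMatrix")
}
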