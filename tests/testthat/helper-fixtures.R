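# Shared fixtures, built in code at test time.

LEX <- load_lexicon()

# filler vocabulary guaranteed free of lexicon keywords
FILLER <- setdiff(
  c("patient", "denies", "reports", "stable", "daily", "review", "clinic",
    "dose", "tablet", "oral", "note", "exam", "plan", "follow", "up",
    "chart", "blood", "pressure", "normal", "visit", "today"),
  LEX$entries$keyword
)

# build an observations data.frame from parallel token/keyword/label lists
make_obs <- function(tokens_list, keywords, labels = NA_character_) {
  n <- length(tokens_list)
  out <- data.frame(
    note_id = sprintf("n%03d", seq_len(n)),
    patient_id = sprintf("p%03d", seq_len(n)),
    token_index = 0L,
    keyword = keywords,
    category = vapply(keywords, function(k) {
      if (k %in% LEX$entries$keyword) keyword_to_category(k, NULL, LEX) else k
    }, ""),
    stringsAsFactors = FALSE
  )
  out$note_date <- as.Date("2016-01-01")
  out$tokens <- tokens_list
  out$label <- rep_len(labels, n)
  out
}

# random token sequence mixing filler words and lexicon keywords
rand_tokens <- function(n, keyword_frac = 0.2) {
  pool_kw <- LEX$entries$keyword
  is_kw <- runif(n) < keyword_frac
  tok <- character(n)
  tok[is_kw] <- sample(pool_kw, sum(is_kw), replace = TRUE)
  tok[!is_kw] <- sample(FILLER, sum(!is_kw), replace = TRUE)
  # randomly upper-case some tokens to exercise case folding
  up <- runif(n) < 0.3
  tok[up] <- toupper(tok[up])
  tok
}

# brute-force matcher: scan every token and compare its case-folded form
# against the keyword set, resolving the category with one-token lookahead
bf_match <- function(tokens, lexicon = LEX) {
  rows <- list()
  for (i in seq_along(tokens)) {
    t <- tolower(tokens[[i]])
    for (k in lexicon$entries$keyword) {
      if (identical(t, k)) {
        nxt <- if (i < length(tokens)) tolower(tokens[[i + 1L]]) else NULL
        rows[[length(rows) + 1L]] <- data.frame(
          keyword = k, token_index = i - 1L,
          category = keyword_to_category(k, nxt, lexicon),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(keyword = character(), token_index = integer(),
                      category = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# small labeled synthetic corpus; wraps generator with test-sized defaults
small_labeled_obs <- function(seed, n_patients = 15L, ...) {
  cfg <- generator_config(n_patients = n_patients, notes_per_patient = 3L,
                          seed = seed, lexicon = LEX, ...)
  co <- generate_corpus(cfg)
  annotate_observations(corpus_observations(co$notes, LEX),
                        co$truth_observations)
}

# tiny linearly separable labeled set: positives share an "active give:"
# bigram, negatives an "allergies:" bigram
separable_obs <- function(n = 40L, seed = 1L) {
  set.seed(seed)
  kw <- sample(c("melatonin", "calcium", "niacin", "fish"), n, replace = TRUE)
  lab <- rep(c("yes", "no"), length.out = n)
  toks <- lapply(seq_len(n), function(i) {
    if (lab[[i]] == "yes") {
      c("(", as.character(i), ")", toupper(kw[[i]]), "5MG", "ACTIVE",
        "Give:", "5MG", "PO", sample(FILLER, 3))
    } else {
      c("ALLERGIES:", "SULFA", ",", toupper(kw[[i]]), sample(FILLER, 3))
    }
  })
  make_obs(toks, kw, lab)
}
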