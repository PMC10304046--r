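# Keyword-centered snippet extraction: every lexicon hit anchors a window
# of +/- `window` tokens (clamped at document edges). Snippets from nearby
# keywords overlap freely; each occurrence keeps its own anchored snippet.

#' Extract keyword-centered snippets from one note
#'
#' Tokenizes the note and emits one snippet per lexicon keyword occurrence:
#' the anchor token plus up to \code{window} tokens of context on each
#' side, clamped at the document boundaries. Overlapping snippets are all
#' kept, ordered by anchor position.
#'
#' @param note Either a character string (the note text) or a list /
#'   one-row data.frame with fields \code{text} and optionally
#'   \code{note_id}, \code{patient_id}, \code{note_date}.
#' @param lexicon A \code{supp_lexicon}.
#' @param window Context width in tokens on each side (default 20).
#' @param dialect A [tokenizer_dialect()].
#' @return A data.frame with one row per keyword occurrence: \code{note_id},
#'   \code{patient_id}, \code{note_date}, \code{anchor_index} (0-based token
#'   position in the document), \code{keyword}, \code{category},
#'   \code{window_start}, \code{window_end} (0-based inclusive token span)
#'   and \code{tokens} (list column of context tokens, original casing).
#' @export
extract_snippets <- function(note, lexicon, window = 20L,
                             dialect = tokenizer_dialect()) {
  stopifnot(inherits(lexicon, "supp_lexicon"), window >= 1L)
  if (is.character(note)) {
    note <- list(text = note)
  }
  if (is.data.frame(note)) {
    stopifnot(nrow(note) == 1L)
    note <- as.list(note)
  }
  note_id <- if (!is.null(note$note_id)) as.character(note$note_id) else NA_character_
  patient_id <- if (!is.null(note$patient_id)) as.character(note$patient_id) else NA_character_
  note_date <- if (!is.null(note$note_date)) as.Date(note$note_date) else as.Date(NA)
  toks <- tokenize(note$text, dialect)
  hits <- match_keywords(toks, lexicon)
  n <- length(toks)
  if (nrow(hits) == 0L) {
    out <- data.frame(note_id = character(), patient_id = character(),
                      anchor_index = integer(), keyword = character(),
                      category = character(), window_start = integer(),
                      window_end = integer(), stringsAsFactors = FALSE)
    out$note_date <- as.Date(character())
    out$tokens <- list()
    return(out[, c("note_id", "patient_id", "note_date", "anchor_index",
                   "keyword", "category", "window_start", "window_end",
                   "tokens")])
  }
  ws <- pmax(0L, hits$token_index - as.integer(window))
  we <- pmin(n - 1L, hits$token_index + as.integer(window))
  out <- data.frame(note_id = note_id, patient_id = patient_id,
                    anchor_index = hits$token_index, keyword = hits$keyword,
                    category = hits$category, window_start = ws,
                    window_end = we, stringsAsFactors = FALSE)
  out$note_date <- note_date
  out$tokens <- lapply(seq_len(nrow(out)), function(i) {
    toks[(ws[[i]] + 1L):(we[[i]] + 1L)]
  })
  out[, c("note_id", "patient_id", "note_date", "anchor_index", "keyword",
          "category", "window_start", "window_end", "tokens")]
}

#' Expand snippets into per-keyword observations
#'
#' One observation per keyword occurrence \emph{inside} each snippet's
#' window: a snippet containing several lexicon hits yields several
#' observations sharing the same context tokens. This is the annotation
#' unit — when a snippet is reviewed, every keyword in it is labeled.
#'
#' @param snippets A data.frame from [extract_snippets()].
#' @param lexicon A \code{supp_lexicon}.
#' @return A data.frame with one row per (snippet, keyword-in-window) pair:
#'   the snippet columns plus \code{snippet_id} (row of origin),
#'   \code{token_index} (document position of this keyword), \code{keyword},
#'   \code{category}, \code{is_anchor}, and \code{label} (NA, to be filled
#'   by annotation).
#' @export
snippet_to_observations <- function(snippets, lexicon) {
  stopifnot(is.data.frame(snippets), inherits(lexicon, "supp_lexicon"))
  if (nrow(snippets) == 0L) {
    out <- snippets
    out$snippet_id <- integer()
    out$token_index <- integer()
    out$is_anchor <- logical()
    out$label <- character()
    return(out)
  }
  pieces <- lapply(seq_len(nrow(snippets)), function(i) {
    sn <- snippets[i, ]
    m <- match_keywords(sn$tokens[[1L]], lexicon)
    doc_index <- sn$window_start + m$token_index
    data.frame(note_id = sn$note_id, patient_id = sn$patient_id,
               note_date = sn$note_date, snippet_id = i,
               anchor_index = sn$anchor_index,
               token_index = doc_index, keyword = m$keyword,
               category = m$category,
               window_start = sn$window_start, window_end = sn$window_end,
               is_anchor = doc_index == sn$anchor_index,
               label = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out$tokens <- snippets$tokens[out$snippet_id]
  rownames(out) <- NULL
  out
}

#' One observation per keyword occurrence across a corpus
#'
#' The classification path: each keyword occurrence anchors its own
#' snippet and is classified exactly once, in that snippet. The number of
#' rows therefore equals the total keyword occurrence count in the corpus.
#'
#' @param notes A data.frame of notes with columns \code{patient_id},
#'   \code{note_date}, \code{text} and optionally \code{note_id} (added as
#'   a row sequence when absent).
#' @param lexicon A \code{supp_lexicon}.
#' @param window Context width in tokens (default 20).
#' @param dialect A [tokenizer_dialect()].
#' @return A data.frame of observations: \code{note_id}, \code{patient_id},
#'   \code{note_date}, \code{token_index}, \code{keyword}, \code{category},
#'   \code{tokens} (list column) and \code{label} (NA until annotated).
#' @export
corpus_observations <- function(notes, lexicon, window = 20L,
                                dialect = tokenizer_dialect()) {
  stopifnot(is.data.frame(notes), "text" %in% names(notes))
  if (!"note_id" %in% names(notes)) {
    notes$note_id <- sprintf("note%06d", seq_len(nrow(notes)))
  }
  pieces <- lapply(seq_len(nrow(notes)), function(i) {
    extract_snippets(notes[i, , drop = FALSE], lexicon, window, dialect)
  })
  sn <- do.call(rbind, pieces)
  if (is.null(sn) || nrow(sn) == 0L) {
    out <- data.frame(note_id = character(), patient_id = character(),
                      token_index = integer(), keyword = character(),
                      category = character(), label = character(),
                      stringsAsFactors = FALSE)
    out$note_date <- as.Date(character())
    out$tokens <- list()
    return(out[, c("note_id", "patient_id", "note_date", "token_index",
                   "keyword", "category", "tokens", "label")])
  }
  out <- data.frame(note_id = sn$note_id, patient_id = sn$patient_id,
                    token_index = sn$anchor_index, keyword = sn$keyword,
                    category = sn$category, stringsAsFactors = FALSE)
  out$note_date <- sn$note_date
  out$tokens <- sn$tokens
  out$label <- NA_character_
  rownames(out) <- NULL
  out[, c("note_id", "patient_id", "note_date", "token_index", "keyword",
          "category", "tokens", "label")]
}

#' Attach ground-truth or manual labels to observations
#'
#' Joins a label table onto observations by (note_id, token_index).
#'
#' @param observations Output of [corpus_observations()] or
#'   [snippet_to_observations()].
#' @param labels A data.frame with \code{note_id}, \code{token_index},
#'   \code{label} ("yes"/"no").
#' @return \code{observations} with the \code{label} column filled.
#' @export
annotate_observations <- function(observations, labels) {
  stopifnot(all(c("note_id", "token_index", "label") %in% names(labels)))
  key_o <- paste(observations$note_id, observations$token_index)
  key_l <- paste(labels$note_id, labels$token_index)
  if (anyDuplicated(key_l)) stop("duplicate (note_id, token_index) in labels")
  idx <- match(key_o, key_l)
  observations$label <- labels$label[idx]
  observations
}

#' Read a note corpus from JSON-lines
#'
#' One JSON object per line with fields \code{patient_id},
#' \code{note_date} (ISO-8601) and \code{text}; \code{note_id} optional.
#'
#' @param path Path to a JSONL file.
#' @return A notes data.frame.
#' @export
read_notes_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON)
  out <- data.frame(
    note_id = vapply(recs, function(r) as.character(r$note_id %||% NA), ""),
    patient_id = vapply(recs, function(r) as.character(r$patient_id), ""),
    text = vapply(recs, function(r) as.character(r$text), ""),
    stringsAsFactors = FALSE
  )
  out$note_date <- as.Date(vapply(recs, function(r) as.character(r$note_date), ""))
  if (all(is.na(out$note_id))) out$note_id <- sprintf("note%06d", seq_len(nrow(out)))
  out[, c("note_id", "patient_id", "note_date", "text")]
}

#' Write a note corpus as JSON-lines
#'
#' @param notes A notes data.frame (\code{note_id}, \code{patient_id},
#'   \code{note_date}, \code{text}).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_notes_jsonl <- function(notes, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(notes))) {
    rec <- list(note_id = notes$note_id[[i]],
                patient_id = notes$patient_id[[i]],
                note_date = format(notes$note_date[[i]]),
                text = notes$text[[i]])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
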