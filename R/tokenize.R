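# Whitespace + punctuation tokenizer that keeps the semi-structural signal
# of clinical notes (asterisk-run med lists, numbered lists, lab panels)
# available to downstream bigram features instead of scrubbing it.

#' Tokenizer dialect options
#'
#' Clinical notes are semi-structured: asterisks separate run-together
#' medication list items ("qday*Glargine"), and colons glue section labels
#' to their heads ("Give:", "ALLERGIES:"). The dialect controls how such
#' markup is tokenized; the defaults isolate asterisks (recovering list
#' structure) and keep trailing colons attached (so "Give:" is one token
#' and section headers stay distinctive features).
#'
#' @param split_asterisk Isolate every \code{*} as its own token.
#' @param isolate_colon Isolate \code{:} as its own token instead of
#'   leaving it attached.
#' @return A list of class \code{supp_dialect}.
#' @export
tokenizer_dialect <- function(split_asterisk = TRUE, isolate_colon = FALSE) {
  stopifnot(is.logical(split_asterisk), is.logical(isolate_colon))
  structure(list(split_asterisk = isTRUE(split_asterisk),
                 isolate_colon = isTRUE(isolate_colon)),
            class = "supp_dialect")
}

#' Tokenize clinical note text
#'
#' Splits on whitespace runs, then separates punctuation glued to words
#' into standalone tokens, with these exceptions: slashes, hyphens and
#' apostrophes flanked by alphanumerics stay intra-word ("CAP/TAB",
#' "QID-INSULIN"), periods between digits stay inside numbers ("0.97"),
#' and trailing colons stay attached by default ("Give:"). Original casing
#' is preserved; matching case-folds separately. Punctuation is kept as
#' tokens, never removed: it is operative signal in semi-structured notes.
#'
#' Re-tokenizing the space-joined token sequence returns the same tokens
#' (idempotence), so token indices are a stable coordinate system.
#'
#' @param text A single character string.
#' @param dialect A [tokenizer_dialect()].
#' @return Character vector of tokens (possibly empty).
#' @examples
#' tokenize("Folic acid 1 mg po qday*Glargine insulin")
#' @export
tokenize <- function(text, dialect = tokenizer_dialect()) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(trimws(text))) return(character())
  s <- text
  # protect intra-word connectives with control-char placeholders
  s <- gsub("(?<=[0-9])\\.(?=[0-9])", "\001", s, perl = TRUE)
  s <- gsub("(?<=[A-Za-z0-9])-(?=[A-Za-z0-9])", "\002", s, perl = TRUE)
  s <- gsub("(?<=[A-Za-z0-9])/(?=[A-Za-z0-9])", "\003", s, perl = TRUE)
  s <- gsub("(?<=[A-Za-z])'(?=[A-Za-z])", "\004", s, perl = TRUE)
  iso <- "\\(\\)\\[\\]\\{\\},;!?\"<>`~|=+"
  if (dialect$split_asterisk) iso <- paste0(iso, "\\*")
  if (dialect$isolate_colon) iso <- paste0(iso, ":")
  s <- gsub(paste0("([", iso, "]|\\.|-|/|')"), " \\1 ", s, perl = TRUE)
  s <- gsub("\001", ".", s, fixed = TRUE)
  s <- gsub("\002", "-", s, fixed = TRUE)
  s <- gsub("\003", "/", s, fixed = TRUE)
  s <- gsub("\004", "'", s, fixed = TRUE)
  toks <- strsplit(trimws(s), "[[:space:]]+")[[1L]]
  toks[nzchar(toks)]
}
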