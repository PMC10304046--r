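# Keyword -> category lexicon: loading, validation, token-level matching.

# Lookahead table for generic vitamin stems: a following token such as "d3"
# or "b12" pins the mention to a specific vitamin category; anything else
# falls back to the stem's own category ("multivitamin").
.vitamin_lookahead <- c(
  "a"   = "vitamin a",
  "b2"  = "vitamin b2",
  "b3"  = "vitamin b3",
  "b6"  = "vitamin b6",
  "b12" = "vitamin b12",
  "c"   = "vitamin c",
  "d"   = "vitamin d3",
  "d2"  = "vitamin d2",
  "d3"  = "vitamin d3"
)

.vitamin_stems <- c("vit", "vita", "vitamin", "vitamine", "vits",
                    "viamin", "viatmin", "vitmain")

#' Path to the packaged supplement lexicon
#'
#' The packaged lexicon maps 83 keyword surface forms (including common
#' misspellings such as "tumeric" and "potasium") to 44 supplement
#' categories.
#'
#' @return Path to the tab-separated lexicon file shipped with the package.
#' @export
default_lexicon_path <- function() {
  system.file("extdata", "supplement_lexicon.tsv", package = "suppuse",
              mustWork = TRUE)
}

#' Load and validate a keyword/category lexicon
#'
#' Reads a two-column tab-separated file with header
#' \code{keyword<TAB>category}. Keywords are single lowercase tokens and
#' must be unique; every category a keyword maps to becomes part of the
#' lexicon's category set.
#'
#' @param path Path to the lexicon file. Defaults to the packaged lexicon.
#' @return An object of class \code{supp_lexicon}: a list with
#'   \code{entries} (data.frame of \code{keyword}, \code{category}) and
#'   \code{categories} (sorted character vector).
#' @examples
#' lex <- load_lexicon()
#' nrow(lex$entries)     # 83 keywords
#' length(lex$categories) # 44 categories
#' @export
load_lexicon <- function(path = default_lexicon_path()) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty lexicon: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) != 2L || !identical(tolower(trimws(header)),
                                         c("keyword", "category"))) {
    stop("lexicon parse error at line 1: expected header 'keyword\\tcategory'")
  }
  body <- lines[-1L]
  if (length(body) == 0L) stop("empty lexicon: ", path)
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad)) {
    stop("lexicon parse error at line ", bad[[1L]] + 1L,
         ": expected 2 tab-separated fields")
  }
  entries <- data.frame(
    keyword  = trimws(vapply(parts, `[[`, "", 1L)),
    category = trimws(vapply(parts, `[[`, "", 2L)),
    stringsAsFactors = FALSE
  )
  entries$keyword <- tolower(entries$keyword)
  entries$category <- tolower(entries$category)
  if (any(!nzchar(entries$keyword)) || any(grepl("\\s", entries$keyword))) {
    stop("lexicon validation error: keywords must be non-empty single tokens")
  }
  if (any(!nzchar(entries$category))) {
    stop("lexicon validation error: empty category name")
  }
  dup <- unique(entries$keyword[duplicated(entries$keyword)])
  if (length(dup)) {
    stop("duplicate keyword(s) in lexicon: ", paste(dup, collapse = ", "))
  }
  entries <- entries[order(entries$keyword), , drop = FALSE]
  rownames(entries) <- NULL
  structure(
    list(entries = entries, categories = sort(unique(entries$category))),
    class = "supp_lexicon"
  )
}

#' @export
print.supp_lexicon <- function(x, ...) {
  cat("Supplement lexicon: ", nrow(x$entries), " keywords, ",
      length(x$categories), " categories\n", sep = "")
  invisible(x)
}

#' Match lexicon keywords in a token sequence
#'
#' Case-insensitive whole-token equality: a token matches iff its
#' case-folded form equals a lexicon keyword. Substring hits (e.g.
#' "calcium" inside "hypocalcemia") never match; conversely "CALCIUM"
#' inside "ATORVASTATIN CALCIUM" does match, because disambiguating drug
#' salts from supplement use is the classifier's job, not the matcher's.
#'
#' @param tokens Character vector of tokens (see [tokenize()]).
#' @param lexicon A \code{supp_lexicon}.
#' @return A data.frame with one row per matching token:
#'   \code{keyword}, \code{token_index} (0-based position), and
#'   \code{category} (resolved with one-token lookahead, see
#'   [keyword_to_category()]). Ordered by \code{token_index}.
#' @export
match_keywords <- function(tokens, lexicon) {
  stopifnot(inherits(lexicon, "supp_lexicon"))
  if (length(tokens) == 0L) {
    return(data.frame(keyword = character(), token_index = integer(),
                      category = character(), stringsAsFactors = FALSE))
  }
  folded <- tolower(tokens)
  hit <- which(folded %in% lexicon$entries$keyword)
  if (length(hit) == 0L) {
    return(data.frame(keyword = character(), token_index = integer(),
                      category = character(), stringsAsFactors = FALSE))
  }
  kw <- folded[hit]
  nxt <- ifelse(hit < length(folded), folded[hit + 1L], NA_character_)
  cat <- vapply(seq_along(kw), function(i) {
    keyword_to_category(kw[[i]], nxt[[i]], lexicon)
  }, "")
  data.frame(keyword = kw, token_index = hit - 1L, category = cat,
             stringsAsFactors = FALSE)
}

#' Resolve a keyword to its supplement category
#'
#' Direct lookup in the lexicon, with one refinement: generic vitamin stems
#' ("vit", "vitamin", ...) inspect the following token — "vitamin d3"
#' resolves to the vitamin d3 category, "vit c" to vitamin c — and fall
#' back to "multivitamin" when the following token is absent or not a
#' recognised vitamin designator.
#'
#' @param keyword A lexicon keyword (case-folded).
#' @param following_token Optional next token in the text (case-folded
#'   internally); used only for vitamin-stem refinement.
#' @param lexicon A \code{supp_lexicon}.
#' @return A single category name.
#' @export
keyword_to_category <- function(keyword, following_token = NULL,
                                lexicon = load_lexicon()) {
  stopifnot(inherits(lexicon, "supp_lexicon"), length(keyword) == 1L)
  keyword <- tolower(keyword)
  i <- match(keyword, lexicon$entries$keyword)
  if (is.na(i)) stop("unknown keyword: ", keyword)
  base <- lexicon$entries$category[[i]]
  if (keyword %in% .vitamin_stems && length(following_token) == 1L &&
      !is.na(following_token)) {
    refined <- unname(.vitamin_lookahead[tolower(following_token)])
    # only refine into categories the lexicon actually carries
    if (!is.na(refined) && refined %in% lexicon$categories) return(refined)
  }
  base
}
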