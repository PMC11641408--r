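#' Tokenize raw post text into normalized word tokens
#'
#' Applies, in order: (1) strip one leading retweet marker of the form
#' `"RT @name:"`; (2) remove URLs; (3) remove `@mention` tokens;
#' (4) transliterate to ASCII and lowercase; (5) delete `#` so hashtag words
#' survive as plain words; (6) replace remaining non-alphanumeric characters
#' with spaces; (7) split on whitespace. Retweets therefore collapse onto
#' their originals, which is what makes word-level edit-distance
#' deduplication treat a retweet as a copy of its source.
#'
#' No stemming and no stop-word removal: downstream comparison is of surface
#' forms only. Non-ASCII characters without a standard Latin decomposition
#' act as token separators.
#'
#' @param text Character vector of raw messages.
#' @return A list of character vectors (one token sequence per input string);
#'   every token matches `[a-z0-9]+`. Empty input gives `character(0)`.
#' @export
#' @examples
#' normalize_text("RT @user: Fluoride is SAFE! https://t.co/xyz")[[1]]
normalize_text <- function(text) {
  x <- as.character(text)
  x[is.na(x)] <- ""
  x <- stringr::str_replace(x, "^\\s*RT @[A-Za-z0-9_]+:\\s*", "")
  x <- stringr::str_replace_all(x, "(?i)(https?://|www\\.)\\S+", " ")
  x <- stringr::str_replace_all(x, "@[A-Za-z0-9_]+", " ")
  x <- stringi::stri_trans_general(x, "Latin-ASCII")
  x <- tolower(x)
  x <- stringr::str_replace_all(x, stringr::fixed("#"), "")
  x <- stringr::str_replace_all(x, "[^a-z0-9]+", " ")
  x <- trimws(x)
  out <- strsplit(x, " ", fixed = TRUE)
  lapply(out, function(t) t[nzchar(t)])
}

#' Extract hashtags from raw text
#'
#' Each maximal `#` + alphanumeric run, lowercased, `#` retained, in order of
#' appearance; duplicates are preserved.
#'
#' @param text Character vector of raw messages.
#' @return A list of character vectors of hashtags, one per input string.
#' @export
#' @examples
#' extract_hashtags("#Caries and #caries")[[1]]
extract_hashtags <- function(text) {
  x <- as.character(text)
  x[is.na(x)] <- ""
  x <- tolower(stringi::stri_trans_general(x, "Latin-ASCII"))
  hits <- stringi::stri_extract_all_regex(x, "#[a-z0-9]+")
  lapply(hits, function(h) if (length(h) == 1 && is.na(h[1])) character(0) else h)
}
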