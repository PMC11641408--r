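#' Word-level Levenshtein distance between token sequences
#'
#' Minimum number of single-token insertions, deletions and substitutions
#' (all unit cost, no transpositions) transforming one token sequence into
#' the other, computed by dynamic programming; tokens are compared by exact
#' string equality. This is a metric on token sequences and reduces to the
#' classical character-level Levenshtein distance when every token is one
#' character.
#'
#' @param a,b Character vectors of tokens (e.g. one element of
#'   [normalize_text()] output).
#' @return Non-negative integer distance.
#' @export
#' @examples
#' word_levenshtein(c("fluoride", "is", "safe"), c("fluoride", "is", "dangerous"))
word_levenshtein <- function(a, b) {
  coded <- tokens_to_int2(list(as.character(a)), list(as.character(b)))
  cpp_word_lev(coded$a[[1]], coded$b[[1]])
}

#' Normalized syntactic similarity of two token sequences
#'
#' `1 - word_levenshtein(a, b) / max(length(a), length(b))`, which lies in
#' \[0, 1\] and equals 1 exactly when the sequences are equal. Two empty
#' sequences have similarity 1 by convention.
#'
#' @inheritParams word_levenshtein
#' @return Similarity in \[0, 1\].
#' @export
#' @examples
#' normalized_similarity(c("a", "b", "c"), c("a", "b", "d"))
normalized_similarity <- function(a, b) {
  coded <- tokens_to_int2(list(as.character(a)), list(as.character(b)))
  cpp_norm_sim(coded$a[[1]], coded$b[[1]])
}

# Similarity matrix between two lists of token sequences (rows = queries).
sim_matrix <- function(queries, refs) {
  coded <- tokens_to_int2(queries, refs)
  cpp_sim_matrix(coded$a, coded$b)
}
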