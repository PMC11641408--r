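# Independent oracles used to validate the implementation, kept deliberately
# naive and separate from the package's code paths.

# Edit distance straight from the recursive definition (no memoisation);
# only usable for very short sequences.
lev_oracle_plain <- function(a, b) {
  if (length(a) == 0) return(length(b))
  if (length(b) == 0) return(length(a))
  cost <- as.integer(a[1] != b[1])
  min(lev_oracle_plain(a[-1], b[-1]) + cost,
      lev_oracle_plain(a[-1], b) + 1L,
      lev_oracle_plain(a, b[-1]) + 1L)
}

# Same recursion with memoisation over suffix pairs, for moderate lengths.
lev_oracle_memo <- function(a, b) {
  na <- length(a); nb <- length(b)
  memo <- matrix(NA_integer_, na + 1, nb + 1)
  rec <- function(i, j) {  # distance between a[i..na] and b[j..nb]
    if (!is.na(memo[i, j])) return(memo[i, j])
    v <- if (i > na) {
      nb - j + 1L
    } else if (j > nb) {
      na - i + 1L
    } else {
      cost <- as.integer(a[i] != b[j])
      min(rec(i + 1, j + 1) + cost, rec(i + 1, j) + 1L, rec(i, j + 1) + 1L)
    }
    memo[i, j] <<- v
    v
  }
  rec(1L, 1L)
}

# All token sequences of length 0..maxlen over an alphabet.
all_token_seqs <- function(alphabet, maxlen) {
  out <- list(character(0))
  for (len in seq_len(maxlen)) {
    grids <- do.call(expand.grid,
                     c(rep(list(alphabet), len), stringsAsFactors = FALSE))
    out <- c(out, lapply(seq_len(nrow(grids)), function(i) {
      unlist(grids[i, ], use.names = FALSE)
    }))
  }
  out
}

count_runs_oracle <- function(x) {
  if (length(x) == 0) return(0L)
  1L + sum(x[-1] != x[-length(x)])
}

# Exact run-count distribution by enumeration of every arrangement of n1
# symbols of one kind and n2 of the other.
runs_dist_enum <- function(n1, n2) {
  n <- n1 + n2
  pos <- utils::combn(n, n1)
  counts <- integer(n)
  for (j in seq_len(ncol(pos))) {
    x <- rep(FALSE, n)
    x[pos[, j]] <- TRUE
    r <- count_runs_oracle(x)
    counts[r] <- counts[r] + 1L
  }
  counts / ncol(pos)
}

# Cohen's kappa for a 2x2 table by the closed form
# 2(ad - bc) / ((a+b)(b+d) + (a+c)(c+d)), an algebraically independent route.
kappa_2x2_closed <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  2 * (a * d - b * c) / ((a + b) * (b + d) + (a + c) * (c + d))
}

# Quick corpus builder: sequential timestamps one hour apart inside the
# default study window.
make_corpus <- function(texts, authors = NULL, genders = NULL,
                        start = "2017-06-01 00:00:00") {
  n <- length(texts)
  if (is.null(authors)) authors <- sprintf("u%03d", seq_len(n))
  if (is.null(genders)) genders <- rep("unknown", n)
  tibble::tibble(
    id = sprintf("t%03d", seq_len(n)),
    text = texts,
    created_at = as.POSIXct(start, tz = "UTC") + 3600 * (seq_len(n) - 1),
    author_id = authors,
    gender = genders
  )
}

# Random token sequence over a small alphabet.
rand_seq <- function(maxlen, alphabet = letters[1:5]) {
  len <- sample(0:maxlen, 1)
  if (len == 0) character(0) else sample(alphabet, len, replace = TRUE)
}
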