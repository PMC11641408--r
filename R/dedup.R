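#' Near-duplicate elimination by greedy leader clustering
#'
#' Records are processed in chronological order (ties broken by id). Each
#' record joins the first existing cluster whose leader has normalized
#' syntactic similarity at least `threshold`, otherwise it founds a new
#' cluster. Retained posts are the cluster leaders, which are pairwise below
#' the threshold by construction; everything else (retweets, bot reposts,
#' near-identical advertisements) is eliminated. A length-ratio prefilter
#' skips the dynamic programme when the metric lower bound already rules the
#' pair out, without changing the result.
#'
#' @param records Corpus tibble (id, text, created_at, author_id, gender).
#' @param threshold Similarity threshold in (0, 1]; default 0.8.
#' @return An object of class `dedup_result`: a list with
#'   \describe{
#'     \item{retained}{tibble of leader records, chronological order}
#'     \item{clusters}{tibble `leader_id`, `member_id`, `similarity`,
#'       `flagged` (every input record appears once; leaders map to
#'       themselves with similarity 1)}
#'     \item{n_input, n_eliminated}{bookkeeping counts}
#'     \item{flagged_nonhuman}{leader ids flagged by [flag_nonhuman()]}
#'   }
#' @export
leader_cluster <- function(records, threshold = 0.8) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    abort("threshold must be a single number in (0, 1]")
  }
  ord <- order(records$created_at, records$id)
  records <- records[ord, , drop = FALSE]
  tokens <- normalize_text(records$text)
  coded <- tokens_to_int(tokens)
  res <- cpp_leader_cluster(coded, threshold)
  leader_ids <- records$id[res$leader]
  is_leader <- res$leader == seq_len(nrow(records))
  clusters <- tibble::tibble(
    leader_id = leader_ids,
    member_id = records$id,
    similarity = res$similarity,
    flagged = FALSE
  )
  structure(
    list(
      retained = records[is_leader, , drop = FALSE],
      clusters = clusters,
      n_input = nrow(records),
      n_eliminated = sum(!is_leader),
      flagged_nonhuman = character(0),
      threshold = threshold
    ),
    class = "dedup_result"
  )
}

#' @export
print.dedup_result <- function(x, ...) {
  cat(sprintf(
    "<dedup_result> %d posts -> %d retained, %d eliminated (threshold %.2f)\n",
    x$n_input, nrow(x$retained), x$n_eliminated, x$threshold))
  if (length(x$flagged_nonhuman) > 0) {
    cat(sprintf("  %d cluster leader(s) flagged non-human\n",
                length(x$flagged_nonhuman)))
  }
  invisible(x)
}

#' Flag probable non-human clusters (advertisements, bot reposts)
#'
#' Clusters whose size (leader included) reaches `min_cluster_size` are
#' flagged as non-human content. By default the flagged leader itself stays
#' in the retained set with the flag recorded; with
#' `drop_leaders = TRUE` flagged leaders are removed as well, so whole
#' advertisement clusters disappear from the corpus.
#'
#' @param result A `dedup_result` from [leader_cluster()].
#' @param min_cluster_size Minimum member count to flag; must be >= 2.
#' @param drop_leaders Also remove flagged leaders from `retained`?
#' @return The updated `dedup_result`.
#' @export
flag_nonhuman <- function(result, min_cluster_size = 3, drop_leaders = FALSE) {
  stopifnot(inherits(result, "dedup_result"))
  if (min_cluster_size < 2) abort("min_cluster_size must be >= 2")
  sizes <- table(result$clusters$leader_id)
  flagged <- names(sizes)[sizes >= min_cluster_size]
  result$flagged_nonhuman <- flagged
  result$clusters$flagged <- result$clusters$leader_id %in% flagged
  if (drop_leaders && length(flagged) > 0) {
    keep <- !(result$retained$id %in% flagged)
    result$n_eliminated <- result$n_eliminated + sum(!keep)
    result$retained <- result$retained[keep, , drop = FALSE]
  }
  result
}

#' Keep one post per author
#'
#' Retains the earliest post (by `created_at`, ties broken by id) of each
#' author, so the final corpus has one post per unique user.
#'
#' @param records Corpus tibble.
#' @return Subset of `records` with unique `author_id`, chronological order.
#' @export
enforce_unique_authors <- function(records) {
  ord <- order(records$created_at, records$id)
  records <- records[ord, , drop = FALSE]
  records[!duplicated(records$author_id), , drop = FALSE]
}
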