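#' Default study keyword set
#'
#' The fifteen lowercase keyword phrases used to identify topical-fluoride
#' posts. A post is retained when its text contains at least one phrase as a
#' case-insensitive contiguous substring.
#'
#' @return Character vector of 15 phrases.
#' @export
#' @examples
#' default_keywords()
default_keywords <- function() {
  c(
    "fluoride", "tooth decay", "child tooth", "pedodontics",
    "paediatric dentistry", "fluoride varnish", "fluoride polish",
    "teeth fluoride", "tooth fluoride", "toothpaste fluoride",
    "teeth varnish", "tooth varnish", "topical fluoride",
    "pineal calcification", "caries risk"
  )
}

#' Validate a keyword set
#'
#' @param phrases Character vector of keyword phrases; lowercased on input.
#' @return The validated lowercase character vector.
#' @export
keyword_set <- function(phrases = default_keywords()) {
  if (length(phrases) == 0) abort("keyword set must be non-empty")
  phrases <- tolower(phrases)
  if (anyDuplicated(phrases)) {
    abort(paste0("duplicate keyword phrases: ",
                 paste(unique(phrases[duplicated(phrases)]), collapse = ", ")))
  }
  phrases
}

valid_genders <- c("female", "male", "unknown")

parse_timestamps <- function(x, context = "created_at") {
  x <- as.character(x)
  ts <- as.POSIXct(x, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                                  "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"),
                   optional = TRUE)
  if (anyNA(ts)) {
    bad <- which(is.na(ts))
    abort(sprintf("unparseable %s at line(s) %s", context,
                  paste(head(bad, 5), collapse = ", ")))
  }
  ts
}

required_fields <- c("id", "text", "created_at", "author_id")

validate_corpus <- function(df, source = "corpus") {
  if (anyNA(df$id) | any(!nzchar(df$id))) {
    abort(sprintf("%s: empty or missing id at line(s) %s", source,
                  paste(head(which(is.na(df$id) | !nzchar(df$id)), 5),
                        collapse = ", ")))
  }
  if (anyDuplicated(df$id)) {
    dup <- unique(df$id[duplicated(df$id)])
    abort(sprintf("%s: duplicate ids: %s", source,
                  paste(head(dup, 10), collapse = ", ")))
  }
  bad <- !(df$gender %in% valid_genders)
  if (any(bad)) {
    abort(sprintf("%s: invalid gender value(s): %s", source,
                  paste(unique(df$gender[bad]), collapse = ", ")))
  }
  df
}

#' Read a post corpus from JSONL or CSV
#'
#' One record per post with fields `id`, `text`, `created_at` (ISO-8601,
#' interpreted as UTC), `author_id` and optional `gender`
#' (`"female"`/`"male"`/`"unknown"`). A missing gender becomes `"unknown"`.
#' Duplicate ids and malformed rows are hard errors naming the offending line.
#'
#' @param path File path.
#' @param format `"jsonl"` (one JSON object per line) or `"csv"` (RFC-4180).
#' @return A tibble with columns `id`, `text`, `created_at` (POSIXct UTC),
#'   `author_id`, `gender`, in file order.
#' @export
read_corpus <- function(path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("corpus file not found: %s", path))
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      obj <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e) {
                        abort(sprintf("malformed JSON at line %d: %s",
                                      i, conditionMessage(e)))
                      })
      missing <- setdiff(required_fields, names(obj))
      if (length(missing) > 0) {
        abort(sprintf("missing field(s) %s at line %d",
                      paste(missing, collapse = ", "), i))
      }
      rows[[i]] <- tibble::tibble(
        id = as.character(obj$id),
        text = as.character(obj$text),
        created_at = as.character(obj$created_at),
        author_id = as.character(obj$author_id),
        gender = if (is.null(obj$gender) || is.na(obj$gender)) "unknown"
                 else as.character(obj$gender)
      )
    }
    df <- dplyr::bind_rows(rows)
  } else {
    df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          trim_ws = FALSE, progress = FALSE)
    missing <- setdiff(required_fields, names(df))
    if (length(missing) > 0) {
      abort(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
    }
    incomplete <- which(Reduce(`|`, lapply(df[required_fields], is.na)))
    if (length(incomplete) > 0) {
      abort(sprintf("missing required value(s) at line(s) %s",
                    paste(head(incomplete + 1, 5), collapse = ", ")))
    }
    if (!"gender" %in% names(df)) df$gender <- "unknown"
    df$gender[is.na(df$gender)] <- "unknown"
    df <- df[, c(required_fields, "gender")]
  }
  df$created_at <- parse_timestamps(df$created_at)
  validate_corpus(tibble::as_tibble(df), source = path)
}

#' Write a post corpus to JSONL or CSV
#'
#' Text round-trips byte-exactly through [read_corpus()], including emoji,
#' `#` and `@` characters and embedded commas/quotes.
#'
#' @param records Corpus tibble as returned by [read_corpus()].
#' @param path Output path.
#' @param format `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(records, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  out <- records
  out$created_at <- format(records$created_at, "%Y-%m-%dT%H:%M:%SZ",
                           tz = "UTC")
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(out)), function(i) {
      jsonlite::toJSON(as.list(out[i, ]), auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    readr::write_csv(out, path, progress = FALSE)
  }
  invisible(path)
}

#' Keep posts containing at least one study keyword
#'
#' Matching is case-insensitive contiguous-substring search on the raw text
#' (before any normalization), mirroring advanced-search semantics. The
#' operation is idempotent and preserves order.
#'
#' @param records Corpus tibble.
#' @param keywords Character vector of phrases (default [default_keywords()]).
#' @return The subset of `records` whose text matches at least one phrase.
#' @export
filter_by_keywords <- function(records, keywords = default_keywords()) {
  keywords <- keyword_set(keywords)
  low <- tolower(records$text)
  keep <- rep(FALSE, length(low))
  for (kw in keywords) {
    keep <- keep | stringi::stri_detect_fixed(low, kw)
  }
  records[keep, , drop = FALSE]
}

#' Calendar quarter of a timestamp within the study window
#'
#' Quarters are half-open three-month intervals starting at `window_start`;
#' the default window 2017-01-01 to 2020-01-01 yields exactly 12 quarters.
#' Timestamps outside `[window_start, window_end)` are an error.
#'
#' @param ts POSIXct vector (UTC) or parseable character.
#' @param window_start,window_end Dates bounding the half-open study window.
#' @return A tibble with columns `year`, `quarter` (1-4) and `label`
#'   (e.g. `"2017-Q1"`), one row per timestamp.
#' @export
#' @examples
#' quarter_of(as.POSIXct("2017-03-31 23:59:59", tz = "UTC"))
quarter_of <- function(ts, window_start = as.Date("2017-01-01"),
                       window_end = as.Date("2020-01-01")) {
  if (is.character(ts)) ts <- parse_timestamps(ts, "timestamp")
  start <- as.POSIXct(paste(window_start, "00:00:00"), tz = "UTC")
  end <- as.POSIXct(paste(window_end, "00:00:00"), tz = "UTC")
  out_of_window <- ts < start | ts >= end
  if (any(out_of_window)) {
    abort(sprintf("%d timestamp(s) outside window [%s, %s)",
                  sum(out_of_window), window_start, window_end))
  }
  lt <- as.POSIXlt(ts, tz = "UTC")
  year <- lt$year + 1900L
  quarter <- lt$mon %/% 3L + 1L
  tibble::tibble(year = year, quarter = quarter,
                 label = sprintf("%d-Q%d", year, quarter))
}

#' All quarters spanned by a study window
#'
#' @inheritParams quarter_of
#' @return Tibble of `year`, `quarter`, `label` in chronological order.
#' @export
quarter_sequence <- function(window_start = as.Date("2017-01-01"),
                             window_end = as.Date("2020-01-01")) {
  starts <- seq(as.Date(window_start), as.Date(window_end), by = "3 months")
  starts <- starts[starts < as.Date(window_end)]
  lt <- as.POSIXlt(starts)
  year <- lt$year + 1900L
  quarter <- lt$mon %/% 3L + 1L
  tibble::tibble(year = year, quarter = quarter,
                 label = sprintf("%d-Q%d", year, quarter))
}

#' Write a result table deterministically
#'
#' Byte-identical output for identical input: stable column order, floats
#' fixed to 4 decimals.
#'
#' @param rows A data frame.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, format = c("csv", "json")) {
  format <- match.arg(format)
  out <- tibble::as_tibble(rows)
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      out[[nm]] <- formatC(out[[nm]], format = "f", digits = 4)
    }
  }
  if (format == "csv") {
    readr::write_csv(out, path, progress = FALSE)
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", na = "null")
  }
  invisible(path)
}

#' Read a result table written by [write_table()]
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`.
#' @return A tibble; numeric-looking columns are converted back to numeric.
#' @export
read_table <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  } else {
    df <- tibble::as_tibble(jsonlite::fromJSON(path))
  }
  for (nm in names(df)) {
    if (is.character(df[[nm]]) &&
        all(grepl("^-?[0-9]+(\\.[0-9]+)?$", df[[nm]]) | is.na(df[[nm]]))) {
      df[[nm]] <- as.numeric(df[[nm]])
    }
  }
  df
}

#' Read a two-rater label file
#'
#' CSV with columns `tweet_id`, `rater_id`, `category`; categories must be
#' one of [categories()].
#'
#' @param path File path.
#' @return Tibble of labels.
#' @export
read_labels <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  missing <- setdiff(c("tweet_id", "rater_id", "category"), names(df))
  if (length(missing) > 0) {
    abort(sprintf("label file missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  bad <- !(df$category %in% categories())
  if (any(bad)) {
    abort(sprintf("unknown category string(s): %s",
                  paste(unique(df$category[bad]), collapse = ", ")))
  }
  tibble::as_tibble(df[, c("tweet_id", "rater_id", "category")])
}
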