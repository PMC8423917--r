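#' Load a word-frequency table
#'
#' SUBTLEX-style two-column TSV: `word<TAB>frequency per million words`.
#' Keys are lowercased; duplicate words and nonpositive or non-numeric
#' frequencies are errors (with the offending line number). Words absent
#' from a frequency table are simply not found on lookup; the analysis
#' pipeline excludes such pairs rather than smoothing.
#'
#' @param path TSV file path.
#' @param language label stored on the table (e.g. `"english"`).
#' @return Data frame of class `frequency_table` with columns `word`,
#'   `per_million` and attribute `language`.
#' @export
load_frequency_table <- function(path, language = NA_character_) {
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  parts <- strsplit(raw, "\t", fixed = TRUE)
  bad_shape <- which(vapply(parts, length, 0L) != 2L)
  if (length(bad_shape) > 0) {
    stop(sprintf("line %d: expected 'word<TAB>per-million'", bad_shape[[1]]))
  }
  word <- tolower(vapply(parts, `[[`, "", 1L))
  fq <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  bad <- which(is.na(fq) | fq <= 0)
  if (length(bad) > 0) {
    stop(sprintf("line %d: frequency must be a positive number, got '%s'",
                 bad[[1]], parts[[bad[[1]]]][[2]]))
  }
  frequency_table(data.frame(word = word, per_million = fq,
                             stringsAsFactors = FALSE), language)
}

#' @rdname load_frequency_table
#' @param df data frame with columns `word` and `per_million`.
#' @export
frequency_table <- function(df, language = NA_character_) {
  stopifnot(all(c("word", "per_million") %in% names(df)))
  df <- df[c("word", "per_million")]
  df$word <- tolower(df$word)
  if (anyDuplicated(df$word)) {
    stop("duplicate word: ", df$word[duplicated(df$word)][[1]])
  }
  if (any(!is.finite(df$per_million) | df$per_million <= 0)) {
    stop("frequencies must be strictly positive")
  }
  attr(df, "language") <- language
  class(df) <- c("frequency_table", "data.frame")
  df
}

#' Look up per-million frequencies
#'
#' @param table a [frequency_table()].
#' @param words character vector.
#' @return Numeric vector of per-million frequencies, `NA` where absent.
#' @export
frequency_lookup <- function(table, words) {
  stopifnot(inherits(table, "frequency_table"))
  table$per_million[match(tolower(words), table$word)]
}

#' Write a frequency table as TSV
#'
#' @param table a [frequency_table()].
#' @param path file path.
#' @export
write_frequency_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Log-transformed frequency
#'
#' Per-million word frequencies are strongly right-skewed, so analyses use
#' their base-10 logarithm.
#'
#' @param f per-million frequency (strictly positive).
#' @return `log10(f)`.
#' @export
log_frequency <- function(f) {
  if (any(!is.finite(f) | f <= 0)) stop("frequency must be strictly positive")
  log10(f)
}

#' Orthographic similarity between two word forms
#'
#' Default measure: one minus the Levenshtein edit distance divided by the
#' length of the longer word, giving a symmetric value in `[0, 1]` (1 for
#' identical forms, 0 when every position differs). Used as a cognateness
#' proxy. The measure is pluggable: pass any
#' `function(w1, w2) -> numeric` to substitute an alternative similarity.
#'
#' @param w1,w2 character vectors of non-empty word forms (recycled to a
#'   common length, compared elementwise).
#' @param method `"levenshtein"` or a custom function.
#' @return Numeric vector of similarities in `[0, 1]`.
#' @export
orthographic_similarity <- function(w1, w2, method = "levenshtein") {
  if (is.function(method)) return(method(w1, w2))
  method <- match.arg(method, "levenshtein")
  if (any(!nzchar(w1)) || any(!nzchar(w2))) stop("empty word form")
  n <- max(length(w1), length(w2))
  w1 <- rep_len(w1, n)
  w2 <- rep_len(w2, n)
  d <- mapply(function(a, b) utils::adist(a, b)[1, 1], w1, w2)
  unname(1 - d / pmax(nchar(w1), nchar(w2)))
}
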