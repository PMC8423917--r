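#' Classify utterances into code-switching types
#'
#' Every utterance is assigned exactly one of three types, using only tokens
#' with unambiguous language identity (a conservative rule: ambiguous tokens
#' never trigger a classification):
#'
#' * `intra_sentential`: the utterance contains at least one unambiguous
#'   token of each language;
#' * `inter_sentential`: otherwise, the utterance contains at least one
#'   unambiguous token in a language not present among the unambiguous
#'   tokens of the immediately preceding utterance (the first utterance can
#'   never be inter-sentential);
#' * `non_cs`: everything else.
#'
#' An utterance with no unambiguous tokens is `non_cs` and contributes an
#' empty language set as a predecessor, so any following utterance with
#' unambiguous content counts as inter-sentential. An utterance following an
#' intra-sentential (two-language) utterance can never be inter-sentential.
#'
#' @param corpus a preprocessed [cs_corpus()].
#' @return A factor of length `n_utterances` with levels
#'   `non_cs`, `intra_sentential`, `inter_sentential`.
#' @export
classify_cs_types <- function(corpus) {
  stopifnot(inherits(corpus, "cs_corpus"))
  n <- corpus$n_utterances
  tk <- corpus$tokens
  has_a <- tapply(tk$lang == "a", tk$utterance, any)
  has_b <- tapply(tk$lang == "b", tk$utterance, any)
  has_a <- as.logical(has_a[as.character(seq_len(n))])
  has_b <- as.logical(has_b[as.character(seq_len(n))])
  has_a[is.na(has_a)] <- FALSE
  has_b[is.na(has_b)] <- FALSE
  types <- rep("non_cs", n)
  types[has_a & has_b] <- "intra_sentential"
  if (n > 1) {
    new_a <- has_a & !c(FALSE, has_a[-n])
    new_b <- has_b & !c(FALSE, has_b[-n])
    inter <- (new_a | new_b) & !(has_a & has_b)
    inter[1] <- FALSE
    types[inter] <- "inter_sentential"
  }
  factor(types, levels = c("non_cs", "intra_sentential", "inter_sentential"))
}

#' Tabulate code-switching types
#'
#' Counts and percentages of sentences per CS type, plus the language
#' composition of word tokens within each type. Token percentages are
#' computed over all tokens of the type's utterances (unambiguous and
#' ambiguous alike), so the two language percentages plus the ambiguous
#' remainder sum to 100.
#'
#' @param types factor from [classify_cs_types()].
#' @param corpus the corpus the types were computed from.
#' @return Data frame with one row per CS type: `cs_type`, `n_sentences`,
#'   `pct_sentences`, `pct_l1`, `pct_l2`, `pct_ambiguous`.
#' @export
count_cs_types <- function(types, corpus) {
  stopifnot(inherits(corpus, "cs_corpus"))
  if (corpus$n_utterances == 0) stop("empty corpus")
  if (length(types) != corpus$n_utterances) {
    stop("types must align with the corpus utterances")
  }
  lv <- levels(types)
  tk <- corpus$tokens
  tok_type <- types[tk$utterance]
  rows <- lapply(lv, function(t) {
    n <- sum(types == t)
    sub <- tk$lang[tok_type == t]
    ntok <- length(sub)
    pct <- function(code) if (ntok > 0) 100 * sum(sub == code) / ntok else NA_real_
    data.frame(cs_type = t, n_sentences = n,
               pct_sentences = 100 * n / length(types),
               pct_l1 = pct("a"), pct_l2 = pct("b"), pct_ambiguous = pct("amb"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Extract switch events
#'
#' A code-switched (CS) word is a word produced in a language different from
#' its immediately preceding word within the same utterance. Events are only
#' recorded when both the word and its predecessor have unambiguous language
#' identities; ambiguous tokens do not transmit language context. Events
#' never cross utterance boundaries.
#'
#' @param corpus a preprocessed [cs_corpus()].
#' @return Data frame with columns `utterance`, `position` (of the CS word),
#'   `cs_form`, `cs_lang`, `prev_form`, `prev_lang`.
#' @export
extract_switch_events <- function(corpus) {
  stopifnot(inherits(corpus, "cs_corpus"))
  tk <- corpus$tokens
  n <- nrow(tk)
  empty <- data.frame(utterance = integer(), position = integer(),
                      cs_form = character(), cs_lang = character(),
                      prev_form = character(), prev_lang = character(),
                      stringsAsFactors = FALSE)
  if (n < 2) return(empty)
  cur <- 2:n
  prev <- cur - 1L
  ok <- tk$utterance[cur] == tk$utterance[prev] &
    tk$lang[cur] %in% c("a", "b") & tk$lang[prev] %in% c("a", "b") &
    tk$lang[cur] != tk$lang[prev]
  if (!any(ok)) return(empty)
  cur <- cur[ok]
  prev <- prev[ok]
  data.frame(utterance = tk$utterance[cur], position = tk$position[cur],
             cs_form = tk$form[cur], cs_lang = tk$lang[cur],
             prev_form = tk$form[prev], prev_lang = tk$lang[prev],
             stringsAsFactors = FALSE)
}

#' Load a word-level translation map
#'
#' A translation map is a static three-column TSV (`word`, `source_lang`,
#' `translation`) giving, for each word in one language, its most likely
#' single translation in the other language. It stands in for an online
#' translation service so the pipeline is reproducible offline. Translations
#' may be multiword phrases; those are excluded downstream, not here.
#'
#' @param path TSV file path.
#' @return Data frame of class `translation_map` with lowercased keys.
#' @export
load_translation_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, quote = "", sep = "\t",
                          col.names = c("word", "source_lang", "translation"),
                          colClasses = "character", fileEncoding = "UTF-8")
  translation_map(df)
}

#' @rdname load_translation_map
#' @param df data frame with columns `word`, `source_lang` (`"a"` or `"b"`),
#'   `translation`.
#' @export
translation_map <- function(df) {
  stopifnot(all(c("word", "source_lang", "translation") %in% names(df)))
  if (!all(df$source_lang %in% c("a", "b"))) {
    stop("source_lang must be 'a' or 'b'")
  }
  df$word <- tolower(df$word)
  df$translation <- tolower(df$translation)
  key <- paste(df$word, df$source_lang)
  if (anyDuplicated(key)) stop("duplicate (word, source_lang) entries")
  class(df) <- c("translation_map", "data.frame")
  df
}

#' Look up translations
#'
#' @param map a [translation_map()].
#' @param words character vector of source words.
#' @param source_lang language code of `words` (recycled).
#' @return Character vector of translations, `NA` where absent.
#' @export
translate <- function(map, words, source_lang) {
  stopifnot(inherits(map, "translation_map"))
  idx <- match(paste(tolower(words), source_lang),
               paste(map$word, map$source_lang))
  map$translation[idx]
}

#' Build unique CS word / translation-equivalent pairs
#'
#' Collapses switch events to unique `(cs_form, cs_lang)` types and pairs
#' each CS word with its translation equivalent (TE) in the other language.
#' CS words whose translation is missing from the map, or whose most likely
#' translation is a multiword phrase, are excluded; exclusions are counted,
#' never raised as errors.
#'
#' @param events data frame from [extract_switch_events()].
#' @param translations a [translation_map()].
#' @return Data frame with columns `cs_form`, `cs_lang`, `te_form`,
#'   `te_lang`, `direction` (`"a-b"` or `"b-a"`), and an attribute
#'   `exclusions`, a named integer vector
#'   (`missing_translation`, `multiword_te`).
#' @export
build_cs_te_pairs <- function(events, translations) {
  stopifnot(inherits(translations, "translation_map"))
  uq <- unique(events[, c("cs_form", "cs_lang")])
  te <- translate(translations, uq$cs_form, uq$cs_lang)
  missing_te <- is.na(te)
  multiword <- !missing_te & grepl("\\s", te)
  keep <- !missing_te & !multiword
  out <- data.frame(
    cs_form = uq$cs_form[keep], cs_lang = uq$cs_lang[keep],
    te_form = te[keep],
    te_lang = ifelse(uq$cs_lang[keep] == "a", "b", "a"),
    stringsAsFactors = FALSE
  )
  out$direction <- paste(out$cs_lang, out$te_lang, sep = "-")
  attr(out, "exclusions") <- c(missing_translation = sum(missing_te),
                               multiword_te = sum(multiword))
  out
}
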