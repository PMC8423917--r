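#' Construct a bilingual code-switching corpus
#'
#' A `cs_corpus` holds an ordered sequence of utterances of language-tagged
#' tokens for one two-language pair. Internally, tokens carry one of three
#' language codes: `"a"` and `"b"` for the two languages of the pair, and
#' `"amb"` for tokens whose language identity is ambiguous (shared forms,
#' proper nouns, mixed morphology). The human-readable language names are
#' stored alongside and used in reports.
#'
#' @param tokens data frame with columns `utterance` (integer, 1-based,
#'   contiguous), `position` (integer, 1-based within utterance), `speaker`
#'   (character or `NA`), `form` (non-empty character, no whitespace), and
#'   `lang` (one of `"a"`, `"b"`, `"amb"`).
#' @param lang_a,lang_b display names of the two languages.
#' @param source free-text provenance string.
#' @return An object of class `cs_corpus`.
#' @export
cs_corpus <- function(tokens, lang_a = "L1", lang_b = "L2", source = "") {
  stopifnot(is.data.frame(tokens))
  required <- c("utterance", "position", "speaker", "form", "lang")
  missing_cols <- setdiff(required, names(tokens))
  if (length(missing_cols) > 0) {
    stop("tokens is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  tokens <- tokens[required]
  tokens$utterance <- as.integer(tokens$utterance)
  tokens$position <- as.integer(tokens$position)
  tokens$form <- as.character(tokens$form)
  tokens$lang <- as.character(tokens$lang)
  if (!all(tokens$lang %in% c("a", "b", "amb"))) {
    stop("token language codes must be one of 'a', 'b', 'amb'")
  }
  if (any(!nzchar(tokens$form)) || any(grepl("\\s", tokens$form))) {
    stop("token forms must be non-empty and contain no whitespace")
  }
  if (nrow(tokens) > 0) {
    ids <- sort(unique(tokens$utterance))
    if (!identical(ids, seq_along(ids))) {
      stop("utterance indices must be contiguous starting at 1")
    }
  }
  structure(
    list(tokens = tokens,
         n_utterances = if (nrow(tokens) > 0) max(tokens$utterance) else 0L,
         lang_a = lang_a, lang_b = lang_b, source = source),
    class = "cs_corpus"
  )
}

#' @export
print.cs_corpus <- function(x, ...) {
  cat(sprintf("<cs_corpus> %s/%s: %d utterances, %d tokens",
              x$lang_a, x$lang_b, x$n_utterances, nrow(x$tokens)))
  tab <- table(factor(x$tokens$lang, levels = c("a", "b", "amb")))
  cat(sprintf(" (%s: %d, %s: %d, ambiguous: %d)\n",
              x$lang_a, tab[["a"]], x$lang_b, tab[["b"]], tab[["amb"]]))
  invisible(x)
}

#' @export
format.cs_corpus <- function(x, ...) {
  sprintf("<cs_corpus %s/%s %d utterances>", x$lang_a, x$lang_b, x$n_utterances)
}

.tag_codes <- c(a = "a", b = "b", amb = "amb")

#' Read a language-tagged bilingual corpus
#'
#' Two on-disk dialects are supported. `"tagged"` expects one utterance per
#' line, tokens as `form/TAG` with `TAG` one of `a`, `b`, `amb`, and an
#' optional leading `speaker<TAB>` field; this mirrors manually annotated
#' transcripts where every word carries a language identity. `"script_detect"`
#' expects plain whitespace-tokenized text and infers each token's language
#' from its Unicode script; it is only meaningful for language pairs written
#' in disjoint scripts (CJK versus Latin), such as Mandarin/English.
#'
#' Forms are lowercased on read so capitalisation variants collapse to one
#' word type.
#'
#' @param path file path, UTF-8.
#' @param format `"tagged"` or `"script_detect"`.
#' @param lang_names length-2 character vector naming languages A and B.
#' @param cjk_lang for `script_detect`, which language code (`"a"` or `"b"`)
#'   is written in the CJK script. Must be supplied explicitly: script
#'   detection between two Latin-script languages is a configuration error.
#' @param source provenance string stored on the corpus.
#' @return A [cs_corpus()].
#' @export
read_corpus <- function(path, format = c("tagged", "script_detect"),
                        lang_names = c("L1", "L2"), cjk_lang = NULL,
                        source = basename(path)) {
  format <- match.arg(format)
  stopifnot(length(lang_names) == 2)
  if (format == "script_detect") {
    if (is.null(cjk_lang) || !cjk_lang %in% c("a", "b")) {
      stop("script_detect requires 'cjk_lang' (\"a\" or \"b\") naming the ",
           "CJK-script language; it cannot separate two Latin-script languages")
    }
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    speaker <- NA_character_
    if (grepl("\t", line, fixed = TRUE)) {
      parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
      speaker <- parts[[1]]
      line <- paste(parts[-1], collapse = " ")
    }
    toks <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(toks) == 0) next
    if (format == "tagged") {
      m <- regmatches(toks, regexec("^(.+)/(a|b|amb)$", toks))
      bad <- vapply(m, length, 0L) != 3L
      if (any(bad)) {
        stop(sprintf("line %d: malformed token '%s' (expected form/TAG with TAG in a|b|amb)",
                     line_no[[i]], toks[which(bad)[1]]))
      }
      forms <- vapply(m, `[[`, "", 2L)
      langs <- vapply(m, `[[`, "", 3L)
    } else {
      forms <- toks
      langs <- detect_language_by_script(toks, cjk_lang = cjk_lang)
    }
    out[[i]] <- data.frame(
      utterance = i, position = seq_along(forms), speaker = speaker,
      form = tolower(forms), lang = langs, stringsAsFactors = FALSE
    )
  }
  tokens <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(tokens)) {
    tokens <- data.frame(utterance = integer(), position = integer(),
                         speaker = character(), form = character(),
                         lang = character(), stringsAsFactors = FALSE)
  } else {
    # renumber in case blank/empty lines were skipped
    tokens$utterance <- match(tokens$utterance, sort(unique(tokens$utterance)))
  }
  cs_corpus(tokens, lang_a = lang_names[[1]], lang_b = lang_names[[2]],
            source = source)
}

#' Write a corpus in the tagged dialect
#'
#' One utterance per line, `form/TAG` tokens, optional `speaker<TAB>` prefix.
#' `read_corpus(write_corpus(x))` is the identity on this dialect.
#'
#' @param corpus a [cs_corpus()].
#' @param path output file path (UTF-8).
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "cs_corpus"))
  tk <- corpus$tokens
  lines <- character(corpus$n_utterances)
  for (u in seq_len(corpus$n_utterances)) {
    rows <- tk[tk$utterance == u, , drop = FALSE]
    body <- paste(paste0(rows$form, "/", rows$lang), collapse = " ")
    sp <- rows$speaker[[1]]
    lines[[u]] <- if (!is.na(sp)) paste0(sp, "\t", body) else body
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Detect a token's language from its Unicode script
#'
#' Classifies each word form by script membership: forms written entirely in
#' Han characters belong to the CJK-script language, forms written entirely
#' in Latin letters (apostrophes and hyphens allowed) to the other, and
#' everything else -- mixed-script forms and all-digit tokens, which carry no
#' language identity -- is ambiguous.
#'
#' @param forms character vector of word forms (non-empty).
#' @param cjk_lang which language code (`"a"` or `"b"`) owns the CJK script.
#' @return Character vector of codes `"a"`, `"b"`, or `"amb"`.
#' @export
detect_language_by_script <- function(forms, cjk_lang = "a") {
  stopifnot(cjk_lang %in% c("a", "b"))
  if (length(forms) == 0) return(character())
  if (any(!nzchar(forms))) stop("empty word form")
  latin_lang <- if (cjk_lang == "a") "b" else "a"
  is_cjk <- grepl("^\\p{Han}+$", forms, perl = TRUE)
  is_latin <- grepl("^[\\p{Latin}'-]+$", forms, perl = TRUE)
  ifelse(is_cjk, cjk_lang, ifelse(is_latin, latin_lang, "amb"))
}

#' Preprocess a corpus
#'
#' Removes non-word markers (e.g. `"<unk>"`), discourse communicators
#' (e.g. `"eh"`), and punctuation-only tokens; strips leading and trailing
#' Unicode punctuation from the remaining forms; lowercases everything; drops
#' utterances emptied by the filtering and renumbers the rest. The operation
#' is idempotent.
#'
#' @param corpus a [cs_corpus()].
#' @param markers character vector of non-word marker forms to remove.
#' @param communicators character vector of discourse-filler forms to remove.
#' @return A new [cs_corpus()] with an attribute `removed`, a named integer
#'   vector of removal counts (`marker`, `communicator`, `punctuation`).
#' @export
preprocess_corpus <- function(corpus, markers = character(),
                              communicators = character()) {
  stopifnot(inherits(corpus, "cs_corpus"))
  tk <- corpus$tokens
  form <- tolower(tk$form)
  drop_set <- tolower(c(markers, communicators))
  is_marker <- form %in% tolower(markers)
  is_comm <- form %in% tolower(communicators)
  stripped <- gsub("^\\p{P}+|\\p{P}+$", "", form, perl = TRUE)
  # re-check the filter sets after stripping attached punctuation ("eh," -> "eh")
  is_marker <- is_marker | stripped %in% tolower(markers)
  is_comm <- is_comm | (stripped %in% tolower(communicators) & !is_marker)
  is_punct <- !is_marker & !is_comm & !nzchar(stripped)
  keep <- !(is_marker | is_comm | is_punct)
  removed <- c(marker = sum(is_marker), communicator = sum(is_comm),
               punctuation = sum(is_punct))
  tk <- tk[keep, , drop = FALSE]
  tk$form <- stripped[keep]
  if (nrow(tk) > 0) {
    tk$utterance <- match(tk$utterance, sort(unique(tk$utterance)))
    tk$position <- stats::ave(seq_len(nrow(tk)), tk$utterance,
                              FUN = seq_along)
  }
  out <- cs_corpus(tk, lang_a = corpus$lang_a, lang_b = corpus$lang_b,
                   source = corpus$source)
  attr(out, "removed") <- removed
  out
}

# utterances as a list of row index vectors, in order
.utterance_rows <- function(corpus) {
  split(seq_len(nrow(corpus$tokens)), corpus$tokens$utterance)
}

# keep a subset of utterances (logical or integer), renumbering
.subset_utterances <- function(corpus, which_utts) {
  ids <- seq_len(corpus$n_utterances)[which_utts]
  tk <- corpus$tokens[corpus$tokens$utterance %in% ids, , drop = FALSE]
  if (nrow(tk) > 0) tk$utterance <- match(tk$utterance, sort(unique(tk$utterance)))
  cs_corpus(tk, lang_a = corpus$lang_a, lang_b = corpus$lang_b,
            source = corpus$source)
}
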