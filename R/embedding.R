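#' Skip-gram embedding configuration
#'
#' Hyperparameters for skip-gram training with negative sampling. The
#' defaults follow the common word2vec settings: 300 dimensions, a context
#' window half-width of five, five epochs, five negative samples per
#' positive, an initial learning rate of 0.025 with linear decay, and no
#' frequency subsampling. `min_count = 1` keeps every word type so networks
#' can be built over the full vocabulary of the selected sentences.
#'
#' @param dim vector dimensionality (>= 2).
#' @param window context window half-width (>= 1). As in word2vec, the
#'   effective window for each position is sampled uniformly from
#'   `1:window`.
#' @param epochs passes over the corpus.
#' @param negative negative samples per positive example.
#' @param min_count minimum token count for a word to enter the vocabulary.
#' @param alpha initial learning rate, linearly decayed to near zero.
#' @param sample frequency-subsampling threshold (0 disables it).
#' @param seed integer RNG seed; training is deterministic given the seed
#'   (single-threaded).
#' @return A list of class `embedding_config`.
#' @export
embedding_config <- function(dim = 300L, window = 5L, epochs = 5L,
                             negative = 5L, min_count = 1L, alpha = 0.025,
                             sample = 0, seed = 1L) {
  stopifnot(dim >= 2, window >= 1, epochs >= 1, negative >= 0,
            min_count >= 1, alpha > 0, sample >= 0)
  structure(list(dim = as.integer(dim), window = as.integer(window),
                 epochs = as.integer(epochs), negative = as.integer(negative),
                 min_count = as.integer(min_count), alpha = alpha,
                 sample = sample, seed = as.integer(seed)),
            class = "embedding_config")
}

#' Train skip-gram word vectors on a corpus
#'
#' Trains word2vec-style skip-gram embeddings with negative sampling on the
#' token stream of a corpus (utterances are the context units; windows never
#' cross utterance boundaries). Words appearing in similar contexts end up
#' close in vector space, so cosine similarities between the resulting
#' vectors serve as semantic association strengths.
#'
#' @param corpus a [cs_corpus()], or a list of character vectors (one
#'   utterance each).
#' @param config an [embedding_config()].
#' @return A numeric matrix, one row per vocabulary word (rownames are the
#'   word forms), `config$dim` columns.
#' @export
train_sgns <- function(corpus, config = embedding_config()) {
  stopifnot(inherits(config, "embedding_config"))
  if (inherits(corpus, "cs_corpus")) {
    sentences <- split(corpus$tokens$form, corpus$tokens$utterance)
  } else if (is.list(corpus)) {
    sentences <- corpus
  } else {
    stop("corpus must be a cs_corpus or a list of character vectors")
  }
  if (length(sentences) == 0) stop("empty corpus")
  all_tokens <- unlist(sentences, use.names = FALSE)
  if (length(all_tokens) == 0) stop("empty corpus")
  counts <- table(all_tokens)
  counts <- counts[counts >= config$min_count]
  if (length(counts) == 0) stop("empty vocabulary after min_count filtering")
  # vocabulary in decreasing count order (ties by name) for stable ids
  ord <- order(-as.numeric(counts), names(counts))
  vocab <- names(counts)[ord]
  vcounts <- as.numeric(counts)[ord]
  ids <- match(all_tokens, vocab) - 1L  # 0-based; NA for dropped words
  lens <- lengths(sentences)
  # encode the stream with -1 sentence separators, dropping OOV tokens
  stream <- integer(length(ids) + length(sentences))
  pos <- 1L
  off <- 0L
  for (k in seq_along(lens)) {
    sent <- ids[(off + 1L):(off + lens[[k]])]
    sent <- sent[!is.na(sent)]
    ns <- length(sent)
    if (ns > 0) {
      stream[pos:(pos + ns - 1L)] <- sent
      pos <- pos + ns
    }
    stream[pos] <- -1L
    pos <- pos + 1L
    off <- off + lens[[k]]
  }
  stream <- stream[seq_len(pos - 1L)]
  emb <- sgns_train_cpp(stream, length(vocab), vcounts,
                        config$dim, config$window, config$epochs,
                        config$negative, config$alpha, config$sample,
                        config$seed)
  rownames(emb) <- vocab
  emb
}

#' Load pretrained word vectors from the one-word-per-line text dialect
#'
#' Reads the common plain-text embedding format: an optional `count dim`
#' header line followed by `word v1 ... vd` lines. When `expected_words` is
#' given, only vectors for those words are parsed and materialised, so large
#' pretrained files can be read with memory proportional to the requested
#' subset.
#'
#' @param path file path.
#' @param expected_words optional character vector; load only these words.
#' @return A numeric matrix with rownames; dimension inferred from the first
#'   vector line.
#' @export
load_vectors <- function(path, expected_words = NULL) {
  con <- file(path, open = "r", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(expected_words)) expected_words <- unique(expected_words)
  dim <- NA_integer_
  words <- character()
  vecs <- list()
  line_no <- 0L
  repeat {
    lines <- readLines(con, n = 10000L, warn = FALSE)
    if (length(lines) == 0) break
    for (line in lines) {
      line_no <- line_no + 1L
      if (!nzchar(trimws(line))) next
      parts <- strsplit(trimws(line), "\\s+")[[1]]
      if (line_no == 1L && length(parts) == 2 &&
          !anyNA(suppressWarnings(as.numeric(parts)))) {
        next  # "count dim" header
      }
      if (is.na(dim)) dim <- length(parts) - 1L
      if (length(parts) - 1L != dim) {
        stop(sprintf("line %d: expected %d vector components, found %d",
                     line_no, dim, length(parts) - 1L))
      }
      w <- parts[[1]]
      if (!is.null(expected_words) && !(w %in% expected_words)) next
      if (w %in% words) {
        warning(sprintf("line %d: duplicate word '%s'; first occurrence kept",
                        line_no, w))
        next
      }
      v <- suppressWarnings(as.numeric(parts[-1]))
      if (anyNA(v)) stop(sprintf("line %d: non-numeric vector component", line_no))
      words[[length(words) + 1L]] <- w
      vecs[[length(vecs) + 1L]] <- v
    }
  }
  if (length(vecs) == 0) {
    return(matrix(numeric(), nrow = 0, ncol = if (is.na(dim)) 0 else dim))
  }
  out <- do.call(rbind, vecs)
  rownames(out) <- words
  out
}

#' Cosine similarity between two vectors
#'
#' The cosine of the angle between two vectors: 1 for parallel vectors, 0
#' for orthogonal ones, -1 for opposite directions. Invariant under positive
#' rescaling of either argument.
#'
#' @param u,v numeric vectors of equal length with nonzero norm.
#' @return A number in `[-1, 1]`.
#' @export
cosine <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero-norm vector")
  max(-1, min(1, sum(u * v) / (nu * nv)))
}
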