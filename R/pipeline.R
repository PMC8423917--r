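# End-to-end study pipelines: community structure of the bilingual lexicon
# (study 1), clustering/frequency effects on switching (study 2), and the
# orthographic-similarity (cognateness) analysis (study 3).

#' Community structure of the bilingual semantic network
#'
#' Builds a weighted semantic network over all unique words of the selected
#' sentences (all sentences, or only the intra-sentential CS sentences),
#' runs Louvain community detection, and summarises the language composition
#' of each community. Nodes are unique word forms; each form is tagged with
#' its modal language tag across the corpus (ties resolved to ambiguous),
#' and ambiguous forms are reported as `"other"`.
#'
#' @param corpus a preprocessed [cs_corpus()].
#' @param embeddings optional embedding matrix; when `NULL`, skip-gram
#'   vectors are trained on the selected sentences with `embedding`.
#' @param embedding an [embedding_config()] used when training here.
#' @param sentence_filter `"all"` or `"intra_only"`.
#' @param seed seed for community detection (and, when training here, the
#'   embedding seed unless `embedding` sets its own).
#' @return A list of class `study1_report`: `cs_types` (type count table for
#'   the full corpus), `sentence_filter`, `n_nodes`, `n_edges`, `partition`
#'   (a `community_partition`), `Q`, `composition` (per-community language
#'   percentages), and `node_tags`.
#' @export
run_study1 <- function(corpus, embeddings = NULL,
                       embedding = embedding_config(dim = 50L),
                       sentence_filter = c("all", "intra_only"), seed = 1L) {
  stopifnot(inherits(corpus, "cs_corpus"))
  sentence_filter <- match.arg(sentence_filter)
  types <- classify_cs_types(corpus)
  type_table <- count_cs_types(types, corpus)
  sub <- if (sentence_filter == "intra_only") {
    .subset_utterances(corpus, types == "intra_sentential")
  } else corpus
  if (nrow(sub$tokens) == 0) stop("sentence filter left no tokens")
  if (is.null(embeddings)) {
    embedding$seed <- as.integer(seed)
    embeddings <- train_sgns(sub, embedding)
  }
  nodes <- .modal_tags(sub)
  net <- build_network(nodes, embeddings)
  part <- louvain(net, seed = seed)
  tags <- stats::setNames(
    ifelse(igraph::V(net)$lang == "a", corpus$lang_a,
           ifelse(igraph::V(net)$lang == "b", corpus$lang_b, "other")),
    igraph::V(net)$name
  )
  comp <- community_composition(part, tags)
  structure(list(cs_types = type_table, sentence_filter = sentence_filter,
                 n_nodes = igraph::vcount(net), n_edges = igraph::ecount(net),
                 partition = part, Q = part$Q, composition = comp,
                 node_tags = tags, network = net),
            class = "study1_report")
}

# unique forms with their modal language tag (ties resolved to ambiguous)
.modal_tags <- function(corpus) {
  tk <- corpus$tokens
  tab <- table(tk$form, factor(tk$lang, levels = c("a", "b", "amb")))
  counts <- as.matrix(tab)
  modal <- apply(counts, 1, function(r) {
    top <- which(r == max(r))
    if (length(top) > 1) "amb" else colnames(counts)[top]
  })
  data.frame(form = rownames(counts), lang = unname(modal),
             stringsAsFactors = FALSE)
}

#' @export
print.study1_report <- function(x, ...) {
  cat(sprintf("<study1_report> filter = %s, %d nodes, %d communities, Q = %.3f\n",
              x$sentence_filter, x$n_nodes, x$partition$n_communities, x$Q))
  print(x$composition, row.names = FALSE)
  invisible(x)
}

#' Clustering-coefficient and frequency effects on code-switching
#'
#' The full paired CS-word / translation-equivalent analysis. Pipeline:
#' extract switch events; collapse to unique CS words per direction and
#' attach translation equivalents (multiword translations excluded); drop
#' pairs whose CS word or TE is missing from the frequency norms; drop
#' pairs missing from the word vectors; build one weighted semantic network
#' per language over the retained CS words and TEs of that language;
#' compute weighted clustering coefficients; z-score them within language;
#' residualize standardized clustering against log frequency (and log
#' frequency against standardized clustering), pooling CS and TE values
#' across both directions; then run the mixed-design ANOVA, per-direction
#' paired t tests, and per-direction sign tests on both residualized
#' measures. Every filter step's count is recorded.
#'
#' @param corpus a preprocessed [cs_corpus()].
#' @param translations a [translation_map()].
#' @param freq_a,freq_b [frequency_table()]s for languages A and B.
#' @param vectors_a,vectors_b embedding matrices for languages A and B (the
#'   same matrix may serve both when vectors were trained on the mixed
#'   bilingual stream).
#' @param min_pairs directions with fewer retained pairs than this are
#'   dropped from the tests with a warning.
#' @return A list of class `study2_report`: `filter_counts`, `pairs` (the
#'   retained pairs with all derived values), `correlation` (pooled Pearson
#'   test between standardized clustering and log frequency), and for each
#'   measure (`res_cz`, `res_logf`): the ANOVA, per-direction paired t
#'   tests, per-direction sign tests, and the pooled mean CS - TE
#'   difference.
#' @export
run_study2 <- function(corpus, translations, freq_a, freq_b,
                       vectors_a, vectors_b, min_pairs = 2L) {
  stopifnot(inherits(corpus, "cs_corpus"),
            inherits(translations, "translation_map"))
  events <- extract_switch_events(corpus)
  pairs <- build_cs_te_pairs(events, translations)
  counts <- c(events = nrow(events), unique_pairs = nrow(pairs))

  freq_of <- function(words, langs) {
    ifelse(langs == "a", frequency_lookup(freq_a, words),
           frequency_lookup(freq_b, words))
  }
  pairs$freq_cs <- freq_of(pairs$cs_form, pairs$cs_lang)
  pairs$freq_te <- freq_of(pairs$te_form, pairs$te_lang)
  pairs <- pairs[!is.na(pairs$freq_cs) & !is.na(pairs$freq_te), , drop = FALSE]
  counts["with_frequency"] <- nrow(pairs)

  has_vec <- function(words, langs) {
    ifelse(langs == "a", words %in% rownames(vectors_a),
           words %in% rownames(vectors_b))
  }
  pairs <- pairs[has_vec(pairs$cs_form, pairs$cs_lang) &
                   has_vec(pairs$te_form, pairs$te_lang), , drop = FALSE]
  counts["with_vectors"] <- nrow(pairs)

  dir_sizes <- table(pairs$direction)
  small <- names(dir_sizes)[dir_sizes < min_pairs]
  if (length(small) > 0) {
    warning("direction(s) with too few pairs dropped: ",
            paste(small, collapse = ", "))
    pairs <- pairs[!pairs$direction %in% small, , drop = FALSE]
  }
  if (nrow(pairs) == 0) stop("no pairs retained")

  # one semantic network per language over that language's CS words and TEs
  measures <- list()
  for (l in c("a", "b")) {
    words <- unique(c(pairs$cs_form[pairs$cs_lang == l],
                      pairs$te_form[pairs$te_lang == l]))
    if (length(words) < 2) next
    vecs <- if (l == "a") vectors_a else vectors_b
    net <- build_network(data.frame(form = words, lang = l,
                                    stringsAsFactors = FALSE), vecs)
    C <- clustering_coefficient(net)
    fq <- if (l == "a") frequency_lookup(freq_a, names(C)) else
      frequency_lookup(freq_b, names(C))
    measures[[l]] <- data.frame(form = names(C), lang = l,
                                C = as.numeric(C),
                                cz = as.numeric(zscore(C)),
                                logf = log_frequency(fq),
                                stringsAsFactors = FALSE)
  }
  node_values <- do.call(rbind, measures)
  key <- paste(node_values$form, node_values$lang)
  val <- function(words, langs, col) {
    node_values[[col]][match(paste(words, langs), key)]
  }
  pairs$cz_cs <- val(pairs$cs_form, pairs$cs_lang, "cz")
  pairs$cz_te <- val(pairs$te_form, pairs$te_lang, "cz")
  pairs$logf_cs <- val(pairs$cs_form, pairs$cs_lang, "logf")
  pairs$logf_te <- val(pairs$te_form, pairs$te_lang, "logf")

  # pooled residualization over the CS and TE values of both directions
  cz_all <- c(pairs$cz_cs, pairs$cz_te)
  lf_all <- c(pairs$logf_cs, pairs$logf_te)
  n <- nrow(pairs)
  res_c <- residualize(cz_all, lf_all)
  res_f <- residualize(lf_all, cz_all)
  pairs$res_cz_cs <- res_c[seq_len(n)]
  pairs$res_cz_te <- res_c[n + seq_len(n)]
  pairs$res_logf_cs <- res_f[seq_len(n)]
  pairs$res_logf_te <- res_f[n + seq_len(n)]

  correlation <- pearson_cor(cz_all, lf_all)

  analyse <- function(cs, te) {
    sample <- paired_sample(cs, te, pairs$direction)
    dirs <- unique(pairs$direction)
    anova <- if (length(dirs) == 2) mixed_anova_2x2(sample) else NULL
    t_tests <- lapply(stats::setNames(dirs, dirs),
                      function(d) paired_t(sample, d))
    signs <- lapply(stats::setNames(dirs, dirs), function(d) {
      s <- sample[sample$direction == d, ]
      lower <- sum(s$value_cs < s$value_te)
      higher <- sum(s$value_cs > s$value_te)
      sign_test(lower, higher)
    })
    list(anova = anova, paired_t = t_tests, sign_tests = signs,
         mean_diff = mean(cs - te))
  }
  structure(list(filter_counts = counts,
                 exclusions = attr(pairs, "exclusions"),
                 pairs = pairs, node_values = node_values,
                 correlation = correlation,
                 res_cz = analyse(pairs$res_cz_cs, pairs$res_cz_te),
                 res_logf = analyse(pairs$res_logf_cs, pairs$res_logf_te)),
            class = "study2_report")
}

#' @export
print.study2_report <- function(x, ...) {
  cat("<study2_report>\n  filter counts: ",
      paste(names(x$filter_counts), x$filter_counts, sep = "=",
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  clustering ~ frequency pooled r = %.3f (p = %.3g)\n",
              x$correlation$estimate, x$correlation$p))
  cat(sprintf("  mean CS-TE difference: Res C_Z = %.4f, Res LogF = %.4f\n",
              x$res_cz$mean_diff, x$res_logf$mean_diff))
  invisible(x)
}

#' Cognateness (orthographic similarity) and switching propensity
#'
#' Every unambiguous word type produced in the corpus is assigned to the CS
#' class if it was ever used as a CS word (any switch event), and to the
#' non-CS class otherwise. Each word's orthographic similarity to its
#' translation equivalent is then used as the predictor in a logistic
#' regression of class membership, quantifying whether cognate-like words
#' are less (negative slope) or more likely to be switched.
#'
#' @param corpus a preprocessed [cs_corpus()].
#' @param translations a [translation_map()].
#' @param similarity similarity function, by default
#'   [orthographic_similarity()].
#' @return A list of class `study3_report` with the logistic `fit` (a
#'   `cs_test`), class counts, and the per-word data frame.
#' @export
run_study3 <- function(corpus, translations, similarity = orthographic_similarity) {
  stopifnot(inherits(corpus, "cs_corpus"),
            inherits(translations, "translation_map"))
  tk <- corpus$tokens
  tk <- tk[tk$lang %in% c("a", "b"), , drop = FALSE]
  words <- unique(tk[, c("form", "lang")])
  events <- extract_switch_events(corpus)
  cs_key <- unique(paste(events$cs_form, events$cs_lang))
  words$is_cs <- paste(words$form, words$lang) %in% cs_key
  words$te <- translate(translations, words$form, words$lang)
  words <- words[!is.na(words$te) & !grepl("\\s", words$te), , drop = FALSE]
  if (nrow(words) < 4) stop("too few words with translations")
  if (length(unique(words$is_cs)) < 2) {
    stop("all words fall in a single class")
  }
  words$similarity <- similarity(words$form, words$te)
  fit <- logistic_fit(words$is_cs, words$similarity)
  structure(list(fit = fit, n_cs = sum(words$is_cs),
                 n_non_cs = sum(!words$is_cs), data = words),
            class = "study3_report")
}

#' @export
print.study3_report <- function(x, ...) {
  cat(sprintf(paste0("<study3_report> %d CS / %d non-CS words; B = %.3f, ",
                     "Wald = %.2f, p = %.3g, R2(Cox-Snell) = %.4f\n"),
              x$n_cs, x$n_non_cs, x$fit$estimate, x$fit$statistic, x$fit$p,
              x$fit$r2_coxsnell))
  invisible(x)
}
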