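# Synthetic bilingual code-switching corpora with planted ground truth.
#
# The generator emulates the statistical structure the analysis pipeline
# assumes in real CS speech: two languages, Zipfian word frequencies, topics
# that induce language-dominant semantic neighbourhoods, a small
# switch-prone lexicon carrying insertional code-switching, ambiguous-
# language tokens, and switching probabilities modulated by the target
# word's contextual diversity (a clustering proxy) and frequency.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(expr)
}

#' Synthetic-corpus generator configuration
#'
#' Parameters of the bilingual corpus generator. Concepts (translation
#' pairs) are assigned Zipfian frequencies and grouped into topics; each
#' topic has a dominant language, and utterances follow a topic with
#' occasional topic shifts. The produced language follows a persistent
#' first-order chain: each token keeps the current language or switches,
#' with the switch probability shaped on the logit scale by `p_stay`, by an
#' attraction towards the topic's dominant language, and by the planted
#' coefficients `beta_C` (on the target form's contextual-concentration
#' proxy for the clustering coefficient) and `beta_F` (on the target form's
#' log frequency). Only a `switchable_fraction` of concepts can be produced
#' in their non-dominant language, reflecting the concentration of
#' insertional switching on a restricted (content-word) lexicon.
#'
#' Contextual diversity is planted per word form: each form has a dispersion
#' in `[0, dispersion_max]`, and a `p_dispersed` share of tokens is drawn
#' from a dispersion-weighted pool of the current language instead of the
#' utterance topic, scattering high-dispersion forms across unrelated
#' contexts. High dispersion means diffuse semantic neighbourhoods, hence
#' low clustering; the concentration proxy entering `beta_C` is the negated
#' standardized dispersion of the form being switched into.
#'
#' @param n_concepts number of concepts (translation pairs).
#' @param n_topics number of topics; concepts are assigned round-robin by
#'   frequency rank, and topics alternate dominant language.
#' @param zipf_exponent exponent of the Zipfian concept-frequency law.
#' @param p_stay probability of keeping the current language at each token
#'   before planted-effect and attraction adjustments; `p_stay = 1` freezes
#'   the chain in its initial language (language A).
#' @param p_ambiguous probability a token is tagged ambiguous.
#' @param utterance_length mean utterance length (Poisson with minimum 1).
#' @param n_utterances number of utterances.
#' @param beta_C planted log-odds coefficient of the target form's
#'   concentration proxy on switching (negative: switching prefers
#'   low-clustering words).
#' @param beta_F planted log-odds coefficient of the target form's log
#'   frequency on switching.
#' @param switchable_fraction fraction of concepts that can be produced in
#'   their non-dominant language.
#' @param dispersion_max upper bound of the per-form dispersion.
#' @param p_dispersed share of tokens drawn from the dispersion pool.
#' @param p_topic_stay probability consecutive utterances keep the topic.
#' @param attraction log-odds boost of returning to the topic's dominant
#'   language for switch-prone concepts.
#' @param attraction_hard the same boost for non-switch-prone concepts
#'   (large, so they are essentially never produced in the non-dominant
#'   language).
#' @param freq_noise_sd standard deviation of the per-form log-frequency
#'   perturbation that differentiates the two languages' frequency norms.
#' @param lang_a_script `"latin"` or `"han"`: script used for language A
#'   forms (language B forms are always Latin).
#' @param lang_names display names for the two languages.
#' @param seed integer RNG seed; generation is fully deterministic given the
#'   configuration.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_concepts = 420L, n_topics = 6L,
                             zipf_exponent = 1, p_stay = 0.8,
                             p_ambiguous = 0.02, utterance_length = 8,
                             n_utterances = 6500L, beta_C = -0.8,
                             beta_F = 0.5, switchable_fraction = 0.06,
                             dispersion_max = 0.6, p_dispersed = 0.15,
                             p_topic_stay = 0.7, attraction = 3,
                             attraction_hard = 7, freq_noise_sd = 0.5,
                             lang_a_script = c("latin", "han"),
                             lang_names = c("L1", "L2"), seed = 1L) {
  lang_a_script <- match.arg(lang_a_script)
  stopifnot(n_concepts >= n_topics, n_topics >= 1, zipf_exponent > 0,
            p_stay >= 0, p_stay <= 1, p_ambiguous >= 0, p_ambiguous <= 1,
            utterance_length >= 1, n_utterances >= 1,
            switchable_fraction >= 0, switchable_fraction <= 1,
            dispersion_max >= 0, dispersion_max <= 1,
            p_dispersed >= 0, p_dispersed < 1,
            p_topic_stay >= 0, p_topic_stay <= 1, freq_noise_sd >= 0)
  structure(list(n_concepts = as.integer(n_concepts),
                 n_topics = as.integer(n_topics),
                 zipf_exponent = zipf_exponent, p_stay = p_stay,
                 p_ambiguous = p_ambiguous,
                 utterance_length = utterance_length,
                 n_utterances = as.integer(n_utterances),
                 beta_C = beta_C, beta_F = beta_F,
                 switchable_fraction = switchable_fraction,
                 dispersion_max = dispersion_max, p_dispersed = p_dispersed,
                 p_topic_stay = p_topic_stay, attraction = attraction,
                 attraction_hard = attraction_hard,
                 freq_noise_sd = freq_noise_sd,
                 lang_a_script = lang_a_script, lang_names = lang_names,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' @rdname generator_config
#' @param ... overrides passed to [generator_config()].
#' @details `seame_like_config()` emulates a Mandarin/English-style corpus:
#'   script-separable languages, no ambiguous tokens, and a high
#'   intra-sentential switching rate. `miami_like_config()` emulates a
#'   Spanish/English-style corpus: both languages in Latin script, a share
#'   of ambiguous tokens, and a much lower switching rate. The two presets
#'   echo the contrast between heavily and lightly switching speech
#'   communities in order of magnitude only.
#' @export
seame_like_config <- function(...) {
  defaults <- list(p_stay = 0.6, p_ambiguous = 0, lang_a_script = "han",
                   lang_names = c("mandarin", "english"))
  do.call(generator_config, utils::modifyList(defaults, list(...)))
}

#' @rdname generator_config
#' @export
miami_like_config <- function(...) {
  defaults <- list(p_stay = 0.95, p_ambiguous = 0.05,
                   lang_a_script = "latin",
                   lang_names = c("spanish", "english"))
  do.call(generator_config, utils::modifyList(defaults, list(...)))
}

# unique pseudo-word forms; Latin strings or two-character Han compounds
.make_forms <- function(n, script, forbidden = character()) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    cand <- if (script == "han") {
      vapply(seq_len(need * 2), function(i) {
        intToUtf8(sample(0x4E00:0x51FF, sample(1:2, 1), replace = TRUE))
      }, "")
    } else {
      vapply(seq_len(need * 2), function(i) {
        paste(sample(letters, sample(4:8, 1), replace = TRUE), collapse = "")
      }, "")
    }
    cand <- setdiff(unique(cand), c(out, forbidden))
    out <- c(out, utils::head(cand, need))
  }
  out
}

#' Generate a synthetic bilingual code-switching corpus
#'
#' Produces a corpus together with its ground truth: the per-concept gold
#' record (forms, topic, home language, switch-proneness, planted dispersion
#' and switching propensities, realized counts), a bijective word-level
#' translation map, and a SUBTLEX-style frequency-norm table per language.
#' Identical configurations (including the seed) produce byte-identical
#' corpora.
#'
#' @param config a [generator_config()].
#' @return A list with elements `corpus` (a [cs_corpus()]), `gold` (data
#'   frame), `translations` (a [translation_map()]), `freq_a`, `freq_b`
#'   ([frequency_table()]s), and `config`.
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  .with_seed(config$seed, .generate_corpus_impl(config))
}

.generate_corpus_impl <- function(cfg) {
  K <- cfg$n_concepts
  Tn <- cfg$n_topics
  # Zipfian concept probabilities; topics assigned round-robin by rank so
  # every topic mixes high- and low-frequency concepts
  p_z <- (seq_len(K))^(-cfg$zipf_exponent)
  p_z <- p_z / sum(p_z)
  topic <- rep_len(seq_len(Tn), K)
  topic_lang <- rep_len(c("a", "b"), Tn)
  home_lang <- topic_lang[topic]

  form_a <- .make_forms(K, cfg$lang_a_script)
  form_b <- .make_forms(K, "latin", forbidden = form_a)

  switchable <- stats::runif(K) < cfg$switchable_fraction
  delta_a <- stats::runif(K, 0, cfg$dispersion_max)
  delta_b <- stats::runif(K, 0, cfg$dispersion_max)

  # per-language frequency norms: shared Zipfian core, per-form log noise
  q_a <- p_z * exp(stats::rnorm(K, 0, cfg$freq_noise_sd))
  q_b <- p_z * exp(stats::rnorm(K, 0, cfg$freq_noise_sd))
  pm_a <- 1e6 * q_a / sum(q_a)
  pm_b <- 1e6 * q_b / sum(q_b)

  z <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
  zc_a <- z(-delta_a)   # concentration proxy of the language-A form
  zc_b <- z(-delta_b)
  zf_a <- z(log10(pm_a))
  zf_b <- z(log10(pm_b))

  base_logit <- stats::qlogis(1 - cfg$p_stay)  # -Inf when p_stay = 1
  logit_into_a <- base_logit + cfg$beta_C * zc_a + cfg$beta_F * zf_a
  logit_into_b <- base_logit + cfg$beta_C * zc_b + cfg$beta_F * zf_b
  p_ins_a <- ifelse(switchable, stats::plogis(logit_into_a), 0)
  p_ins_b <- ifelse(switchable, stats::plogis(logit_into_b), 0)
  p_ret_a <- stats::plogis(logit_into_a +
                             ifelse(switchable, cfg$attraction, cfg$attraction_hard))
  p_ret_b <- stats::plogis(logit_into_b +
                             ifelse(switchable, cfg$attraction, cfg$attraction_hard))

  topic_concepts <- split(seq_len(K), topic)
  topic_probs <- lapply(topic_concepts, function(idx) p_z[idx] / sum(p_z[idx]))
  # dispersion pools per language: home forms plus switch-prone guest forms
  pool_a <- which(home_lang == "a" | switchable)
  pool_b <- which(home_lang == "b" | switchable)
  pw_a <- p_z[pool_a] * delta_a[pool_a]
  pw_b <- p_z[pool_b] * delta_b[pool_b]
  has_pool_a <- sum(pw_a) > 0
  has_pool_b <- sum(pw_b) > 0

  n_utt <- cfg$n_utterances
  lens <- pmax(1L, stats::rpois(n_utt, cfg$utterance_length - 1) + 1L)
  total <- sum(lens)
  utt_col <- rep.int(seq_len(n_utt), lens)
  pos_col <- sequence(lens)
  concept_col <- integer(total)
  lang_col <- character(total)

  cur_lang <- "a"
  cur_topic <- sample.int(Tn, 1)
  i <- 0L
  for (u in seq_len(n_utt)) {
    if (stats::runif(1) >= cfg$p_topic_stay) cur_topic <- sample.int(Tn, 1)
    dom <- topic_lang[[cur_topic]]
    for (tok in seq_len(lens[[u]])) {
      i <- i + 1L
      if (stats::runif(1) < cfg$p_dispersed &&
          ((cur_lang == "a" && has_pool_a) || (cur_lang == "b" && has_pool_b))) {
        # diverse-context emission: dispersion-weighted, any topic
        con <- if (cur_lang == "a") {
          pool_a[sample.int(length(pool_a), 1, prob = pw_a)]
        } else {
          pool_b[sample.int(length(pool_b), 1, prob = pw_b)]
        }
      } else {
        idx <- topic_concepts[[cur_topic]]
        con <- idx[sample.int(length(idx), 1, prob = topic_probs[[cur_topic]])]
        if (cur_lang == dom) {
          p_sw <- if (dom == "a") p_ins_b[[con]] else p_ins_a[[con]]
          if (stats::runif(1) < p_sw) cur_lang <- if (dom == "a") "b" else "a"
        } else {
          p_ret <- if (dom == "a") p_ret_a[[con]] else p_ret_b[[con]]
          if (stats::runif(1) < p_ret) cur_lang <- dom
        }
      }
      concept_col[[i]] <- con
      lang_col[[i]] <- cur_lang
    }
  }

  form_col <- ifelse(lang_col == "a", form_a[concept_col], form_b[concept_col])
  tag_col <- lang_col
  if (cfg$p_ambiguous > 0) {
    amb <- stats::runif(total) < cfg$p_ambiguous
    tag_col[amb] <- "amb"
  }

  tokens <- data.frame(utterance = utt_col, position = pos_col,
                       speaker = NA_character_, form = form_col,
                       lang = tag_col, stringsAsFactors = FALSE)
  corpus <- cs_corpus(tokens, lang_a = cfg$lang_names[[1]],
                      lang_b = cfg$lang_names[[2]],
                      source = sprintf("synthetic (seed %d)", cfg$seed))

  count_a <- tabulate(concept_col[lang_col == "a"], nbins = K)
  count_b <- tabulate(concept_col[lang_col == "b"], nbins = K)
  gold <- data.frame(
    concept = seq_len(K), form_a = form_a, form_b = form_b, topic = topic,
    home_lang = home_lang, switchable = switchable,
    dispersion_a = delta_a, dispersion_b = delta_b,
    per_million_a = pm_a, per_million_b = pm_b,
    propensity_into_a = logit_into_a, propensity_into_b = logit_into_b,
    count_a = count_a, count_b = count_b,
    stringsAsFactors = FALSE
  )
  translations <- translation_map(data.frame(
    word = c(form_a, form_b), source_lang = rep(c("a", "b"), each = K),
    translation = c(form_b, form_a), stringsAsFactors = FALSE
  ))
  freq_a <- frequency_table(data.frame(word = form_a, per_million = pm_a,
                                       stringsAsFactors = FALSE),
                            cfg$lang_names[[1]])
  freq_b <- frequency_table(data.frame(word = form_b, per_million = pm_b,
                                       stringsAsFactors = FALSE),
                            cfg$lang_names[[2]])
  list(corpus = corpus, gold = gold, translations = translations,
       freq_a = freq_a, freq_b = freq_b, config = cfg)
}

#' Generate a paired CS/TE sample with a planted effect
#'
#' Simulates per-item CS and TE measurements with a planted mean difference
#' (`value_cs - value_te = delta` on average) on top of an item-level random
#' baseline, for exercising the paired statistics under a known truth.
#'
#' @param n_items number of items (>= 2).
#' @param delta planted mean CS - TE difference.
#' @param sigma within-item noise standard deviation (> 0).
#' @param seed integer RNG seed.
#' @param directions labels of the two direction groups.
#' @param prop proportion of items in the first direction.
#' @return A [paired_sample()].
#' @export
generate_paired_sample <- function(n_items, delta = 0, sigma = 1, seed = 1L,
                                   directions = c("a-b", "b-a"), prop = 0.5) {
  stopifnot(n_items >= 2, sigma > 0, prop >= 0, prop <= 1)
  .with_seed(seed, {
    base <- stats::rnorm(n_items)
    te <- base + stats::rnorm(n_items, 0, sigma)
    cs <- base + delta + stats::rnorm(n_items, 0, sigma)
    n1 <- round(prop * n_items)
    dir <- rep(directions, c(n1, n_items - n1))
    paired_sample(cs, te, dir)
  })
}
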