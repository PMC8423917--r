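test_that("generation is deterministic and writes byte-identical corpora", {
  g1 <- generate_corpus(seame_like_config(seed = 5, n_utterances = 300L))
  g2 <- generate_corpus(seame_like_config(seed = 5, n_utterances = 300L))
  expect_identical(g1$corpus, g2$corpus)
  expect_identical(g1$gold, g2$gold)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_corpus(g1$corpus, f1)
  write_corpus(g2$corpus, f2)
  expect_identical(readLines(f1, encoding = "UTF-8"),
                   readLines(f2, encoding = "UTF-8"))
  g3 <- generate_corpus(seame_like_config(seed = 6, n_utterances = 300L))
  expect_false(identical(g1$corpus$tokens, g3$corpus$tokens))
})

test_that("a frozen language chain yields a monolingual non-CS corpus", {
  g <- generate_corpus(generator_config(p_stay = 1, p_ambiguous = 0,
                                        n_utterances = 400L, seed = 3))
  expect_equal(unique(g$corpus$tokens$lang), "a")
  expect_equal(nrow(extract_switch_events(g$corpus)), 0)
  types <- classify_cs_types(g$corpus)
  expect_true(all(types == "non_cs"))
})

test_that("ambiguity and translation invariants hold", {
  g <- generate_corpus(generator_config(p_ambiguous = 0, n_utterances = 300L,
                                        seed = 4))
  expect_false("amb" %in% g$corpus$tokens$lang)
  # translation map is bijective over concepts, both directions present
  tm <- g$translations
  expect_equal(nrow(tm), 2 * nrow(g$gold))
  expect_setequal(tm$translation[tm$source_lang == "a"], g$gold$form_b)
  expect_setequal(tm$translation[tm$source_lang == "b"], g$gold$form_a)
  # every emitted form is in the gold record
  expect_true(all(g$corpus$tokens$form %in% c(g$gold$form_a, g$gold$form_b)))
  # frequency norms strictly positive
  expect_true(all(g$freq_a$per_million > 0) && all(g$freq_b$per_million > 0))
})

test_that("realized rank-frequency follows the configured Zipf law", {
  g <- generate_corpus(generator_config(seed = 7))  # ~50k tokens
  cnt <- sort(g$gold$count_a + g$gold$count_b, decreasing = TRUE)
  cnt <- cnt[cnt > 0]
  slope <- unname(coef(lm(log(cnt) ~ log(seq_along(cnt))))[2])
  expect_lt(abs(slope - (-1)), 0.15)
})

test_that("the intra-sentential rate decreases in p_stay", {
  rates <- vapply(c(0.5, 0.8, 0.95), function(ps) {
    g <- generate_corpus(generator_config(p_stay = ps, seed = 9,
                                          n_utterances = 2000L))
    mean(classify_cs_types(g$corpus) == "intra_sentential")
  }, 0)
  expect_true(all(diff(rates) < 0))
})

test_that("CS-word selection recovers the sign of the planted clustering effect", {
  # With beta_C < 0, switching prefers targets with low contextual
  # concentration (high dispersion); flipping the sign must flip the planted
  # dispersion contrast of the realized CS words.
  mean_cs_dispersion <- function(beta_C, seed) {
    g <- generate_corpus(seame_like_config(seed = seed, beta_C = beta_C,
                                           beta_F = 0, n_utterances = 3000L))
    ev <- extract_switch_events(g$corpus)
    uq <- unique(ev[, c("cs_form", "cs_lang")])
    disp <- ifelse(uq$cs_lang == "a",
                   g$gold$dispersion_a[match(uq$cs_form, g$gold$form_a)],
                   g$gold$dispersion_b[match(uq$cs_form, g$gold$form_b)])
    pool <- c(g$gold$dispersion_a, g$gold$dispersion_b)
    mean(disp) - mean(pool)
  }
  neg <- mean_cs_dispersion(-2, seed = 11)
  pos <- mean_cs_dispersion(+2, seed = 11)
  expect_gt(neg, pos)  # beta_C < 0 selects high-dispersion (low-C) words
  expect_gt(neg, 0)
})

test_that("paired samples carry the planted difference and direction mix", {
  s <- generate_paired_sample(200, delta = -0.5, sigma = 0.5, seed = 2,
                              prop = 0.3)
  expect_s3_class(s, "paired_sample")
  expect_equal(nrow(s), 200)
  expect_equal(sum(s$direction == "a-b"), 60)
  expect_lt(mean(s$value_cs - s$value_te), 0)
  tiny <- generate_paired_sample(2, delta = 0, sigma = 1, seed = 1)
  expect_equal(nrow(tiny), 2)
  expect_error(generate_paired_sample(1, 0, 1), ">= 2")
})

test_that("planted effects reach high power in the paired t", {
  # delta = -0.5*sigma at n = 200: noncentral-t power is essentially 1
  rej <- vapply(1:60, function(s) {
    p <- paired_t(generate_paired_sample(200, delta = -0.5, sigma = 1,
                                         seed = 1000 + s))$p
    p < 0.05
  }, TRUE)
  expect_gte(mean(rej), 0.95)
})

test_that("generator configs validate their arguments", {
  expect_error(generator_config(p_stay = 1.4), "p_stay")
  expect_error(generator_config(n_concepts = 3, n_topics = 5), "n_concepts")
  expect_error(generator_config(zipf_exponent = 0), "zipf")
})
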