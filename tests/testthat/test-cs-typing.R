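mk_intra <- function() {
  paste0(zh$gangcai, "/a ", zh$wo, "/a ", zh$bushi, "/a ", zh$gen, "/a ",
         zh$ni, "/a ", zh$jiang, "/a ", zh$wo, "/a apply/b ", zh$nage,
         "/a job/b")
}

test_that("the three CS types are classified by the unambiguous-token rule", {
  corp <- corpus_from_lines(c(
    "are/b you/b sure/b",
    "actually/b i/b do/b not/b think/b that's/b necessary/b",
    mk_intra(),
    paste0(zh$wo, "/a ", zh$yao, "/a ", zh$huijia, "/a ", zh$kan, "/a"),
    "it/b was/b exciting/b once/b"
  ), lang_a = "mandarin", lang_b = "english")
  types <- classify_cs_types(corp)
  # the all-Mandarin utterance follows an intra-sentential one (both
  # languages present), so it introduces no new language; the final English
  # utterance after a Mandarin-only one is the inter-sentential case
  expect_equal(as.character(types),
               c("non_cs", "non_cs", "intra_sentential", "non_cs",
                 "inter_sentential"))
})

test_that("the first utterance is never inter-sentential and ambiguous tokens never classify", {
  corp <- corpus_from_lines(c("hola/a tal/a", "no/amb", "ya/b done/b"))
  types <- classify_cs_types(corp)
  # utterance 2 has no unambiguous tokens -> non_cs; utterance 3 introduces
  # language b against an empty predecessor set -> inter
  expect_equal(as.character(types),
               c("non_cs", "non_cs", "inter_sentential"))
  first <- classify_cs_types(corpus_from_lines("solo/a espanol/a"))
  expect_equal(as.character(first), "non_cs")
})

test_that("an utterance after an intra-sentential one is never inter-sentential", {
  corp <- corpus_from_lines(c("mix/a of/b both/b", "solo/a uno/a"))
  expect_equal(as.character(classify_cs_types(corp)),
               c("intra_sentential", "non_cs"))
})

test_that("type counts and token percentages tally on a hand-labelled fixture", {
  corp <- corpus_from_lines(c(
    "uno/a dos/a",            # non_cs
    "one/b two/b",            # inter
    "tres/a four/b",          # intra
    "cinco/a seis/a",         # non_cs (follows intra)
    "siete/a no/amb",         # non_cs
    "eight/b nine/b"          # inter
  ))
  types <- classify_cs_types(corp)
  tab <- count_cs_types(types, corp)
  expect_equal(tab$n_sentences, c(3L, 1L, 2L))
  expect_equal(tab$pct_sentences, c(50, 100 / 6, 100 / 3))
  expect_equal(sum(tab$n_sentences), corp$n_utterances)
  expect_equal(sum(tab$pct_sentences), 100, tolerance = 1e-9)
  # non_cs tokens: uno dos cinco seis siete no -> 5 of 6 in language a
  expect_equal(tab$pct_l1[[1]], 500 / 6, tolerance = 1e-9)
  expect_equal(tab$pct_ambiguous[[1]], 100 / 6, tolerance = 1e-9)
  row_sums <- rowSums(tab[, c("pct_l1", "pct_l2", "pct_ambiguous")])
  expect_equal(row_sums, rep(100, 3), tolerance = 0.1, ignore_attr = TRUE)
  expect_error(count_cs_types(types, corpus_from_lines(character())), "empty")
})

test_that("an all-monolingual corpus is 100% non-CS", {
  corp <- corpus_from_lines(c("a/a b/a", "c/a d/a", "e/a"))
  tab <- count_cs_types(classify_cs_types(corp), corp)
  expect_equal(tab$pct_sentences, c(100, 0, 0))
})

test_that("switch events fire on adjacent unambiguous cross-language tokens only", {
  corp <- corpus_from_lines(mk_intra(), lang_a = "mandarin", lang_b = "english")
  ev <- extract_switch_events(corp)
  expect_equal(ev$cs_form, c("apply", zh$nage, "job"))
  expect_equal(ev$cs_lang, c("b", "a", "b"))
  expect_true(all(ev$position >= 2))
  expect_true(all(ev$cs_lang != ev$prev_lang))

  mono <- extract_switch_events(corpus_from_lines("just/b english/b here/b"))
  expect_equal(nrow(mono), 0)

  amb <- extract_switch_events(corpus_from_lines("word/b no/amb casa/a"))
  expect_equal(nrow(amb), 0)  # ambiguous tokens do not transmit context

  boundary <- extract_switch_events(corpus_from_lines(c("ingles/b", "casa/a")))
  expect_equal(nrow(boundary), 0)  # events never cross utterances
})

test_that("CS-TE pairs are unique per direction with logged exclusions", {
  corp <- corpus_from_lines(c(
    paste0(zh$wo, "/a job/b ", zh$nage, "/a job/b"),
    paste0(zh$wo, "/a good/b ", zh$ligong, "/a"),
    paste0(zh$wo, "/a mystery/b")
  ), lang_a = "mandarin", lang_b = "english")
  ev <- extract_switch_events(corp)
  map <- translation_map(data.frame(
    word = c("job", zh$nage, zh$ligong, "good"),
    source_lang = c("b", "a", "a", "b"),
    translation = c(zh$gangcai, "that", "science and technology", zh$kan)
  ))
  pairs <- build_cs_te_pairs(ev, map)
  # "job" switched twice -> one record; "mystery" unmapped; the word whose
  # translation is a multiword phrase is excluded
  expect_equal(sort(pairs$cs_form), sort(c("job", zh$nage, "good")))
  excl <- attr(pairs, "exclusions")
  expect_equal(unname(excl["missing_translation"]), 1L)
  expect_equal(unname(excl["multiword_te"]), 1L)
  expect_equal(pairs$direction[pairs$cs_form == "job"], "b-a")
  expect_equal(pairs$direction[pairs$cs_form == zh$nage], "a-b")
  # directions partition the records disjointly
  expect_false(any(duplicated(pairs[, c("cs_form", "cs_lang")])))
})

test_that("every intra utterance yields a switch event unless ambiguity blocks it", {
  gen <- generate_corpus(seame_like_config(seed = 42, n_utterances = 400L))
  types <- classify_cs_types(gen$corpus)
  ev <- extract_switch_events(gen$corpus)
  intra_utts <- which(types == "intra_sentential")
  expect_true(all(intra_utts %in% ev$utterance))  # p_ambiguous = 0 here
})
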