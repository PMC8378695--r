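test_that("tokenization lowercases, normalizes and splits on delimiters", {
  expect_equal(tokenize("Two words."), c("two", "words"))
  expect_equal(tokenize("end—start"), c("end", "start"))
  expect_equal(tokenize(""), character(0))
  expect_equal(tokenize("l'arbre-rouge 42 fois"),
               c("l", "arbre", "rouge", "fois"))
})

test_that("token filtering keeps only table-alphabet words", {
  out <- filter_tokens(c("casa", "naïve2"))
  expect_equal(out$tokens, "casa")
  expect_equal(out$n_excluded, 1L)
  expect_equal(filter_tokens(c("casa", "perro"))$n_excluded, 0L)
  # ß is a fricative grapheme, so the token survives
  expect_equal(filter_tokens("ß")$tokens, "ß")
})

test_that("word measurement yields m, g and y = g/m", {
  meas <- measure_words(c("barco", "a"))
  expect_equal(meas$m, c(2L, 1L))
  expect_equal(meas$g, c(5L, 1L))
  expect_equal(meas$y, c(2.5, 1.0))
  # vowel-free tokens dropped by default, kept on request
  expect_equal(nrow(measure_words(c("pst", "casa"))), 1L)
  kept <- measure_words(c("pst", "casa"), exclude_vowel_free = FALSE)
  expect_equal(kept$m, c(1L, 2L))
})

test_that("the two aggregation methods differ exactly as in the two-book toy", {
  # book one: a hundred 1-grapheme monosyllables; book two: one 2-grapheme
  # monosyllable. Pooled mean at m = 1 is 102/101; per-book averaging gives
  # (1 + 2)/2 = 1.5.
  meas <- dplyr::bind_rows(
    measure_words(rep("a", 100), doc = "book1"),
    measure_words("aa", doc = "book2")
  )
  pooled <- profile_full_corpus(meas, min_count = 1,
                                include_monosyllables = TRUE)
  by_doc <- profile_by_document(meas, min_count = 1,
                                include_monosyllables = TRUE)
  expect_equal(pooled$mean_y, 102 / 101)
  expect_equal(by_doc$mean_y, 1.5)
  expect_equal(pooled$count, 101L)
  expect_equal(by_doc$count, 101L)
})

test_that("profiles honour the support filter and monosyllable exclusion", {
  meas <- measure_words(rep("cava", 30))
  prof <- profile_full_corpus(meas, min_count = 1)
  expect_equal(prof$m, 2L)
  expect_equal(prof$mean_y, 2.0)
  expect_equal(prof$count, 30L)
  # bin below threshold -> empty profile
  expect_equal(nrow(profile_full_corpus(meas, min_count = 31)), 0L)
  # monosyllables dropped unless requested
  mono <- measure_words(rep("a", 30))
  expect_equal(nrow(profile_full_corpus(mono, min_count = 1)), 0L)
  expect_equal(nrow(profile_full_corpus(mono, min_count = 1,
                                        include_monosyllables = TRUE)), 1L)
})

test_that("per-document averaging reduces to pooling for one document", {
  words <- generate_ssp_words(800, seed = 3, max_syllables = 5)$word
  meas <- measure_words(words, doc = "only")
  pooled <- profile_full_corpus(meas, min_count = 1,
                                include_monosyllables = TRUE)
  by_doc <- profile_by_document(meas, min_count = 1,
                                include_monosyllables = TRUE)
  expect_equal(as.data.frame(by_doc), as.data.frame(pooled))
  # duplicating the document leaves the by-document profile unchanged
  meas2 <- dplyr::bind_rows(meas,
                            dplyr::mutate(meas, doc = "copy"))
  by_doc2 <- profile_by_document(meas2, min_count = 1,
                                 include_monosyllables = TRUE)
  expect_equal(by_doc2$mean_y, by_doc$mean_y)
})

test_that("profile counts plus exclusion tallies conserve the token total", {
  words <- generate_ssp_words(600, seed = 21, max_syllables = 6)$word
  meas <- measure_words(words)
  min_count <- 25
  prof <- profile_full_corpus(meas, min_count = min_count)
  by_m <- dplyr::count(meas, m)
  monosyllables <- sum(by_m$n[by_m$m == 1])
  below <- sum(by_m$n[by_m$m >= 2 & by_m$n < min_count])
  expect_equal(sum(prof$count) + monosyllables + below, nrow(meas))
})

test_that("corpus summary counts symbols with one delimiter per token", {
  s <- corpus_summary("casa casa")
  expect_equal(s$tokens, 2)
  expect_equal(s$consonants, 4)
  expect_equal(s$vowels, 4)
  expect_equal(s$syllables, 4)
  expect_equal(s$syll_v_ratio, 1.0)
  expect_equal(s$p_v + s$p_c + s$p_s, 1)
  empty <- corpus_summary("")
  expect_equal(empty$tokens, 0)
  expect_true(is.na(empty$p_c))
  expect_true(is.na(empty$syll_v_ratio))
})

test_that("the rank correlation test flags monotone profiles at the sign", {
  cv <- null_curve(0.48)
  prof <- tibble::tibble(m = 2:8, mean_y = null_mean_length(cv, 2:8))
  res <- spearman_menzerath(prof)
  expect_identical(res$rho, -1)
  expect_lt(res$p_value, 0.01)

  up <- tibble::tibble(m = 1:6, mean_y = seq(1, 2, length.out = 6))
  expect_identical(spearman_menzerath(up)$rho, 1)

  flat <- tibble::tibble(m = 1:5, mean_y = rep(2, 5))
  expect_equal(spearman_menzerath(flat)$rho, 0)
  expect_equal(spearman_menzerath(flat)$p_value, 1)

  expect_error(spearman_menzerath(prof[1:2, ]), "at least 3")
})

test_that("pipeline segmentation matches the null model by construction", {
  p <- source_params(0.48, 0.37)
  rendered <- render_memoryless_text(p, 5000, seed = 17)
  from_stream <- segment_words(rendered$symbols, clusters = FALSE)
  tokens <- filter_tokens(tokenize(rendered$text))$tokens
  counts <- token_cv_counts(tokens)
  expect_equal(length(tokens), nrow(from_stream))
  expect_equal(counts$n, from_stream$n)
  expect_equal(counts$m, from_stream$m)
})
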