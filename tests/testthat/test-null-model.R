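test_that("the null curve satisfies a = p_c/(1-p_c), b = a + 1", {
  c0 <- null_curve(0)
  expect_equal(c0$a, 0)
  expect_equal(c0$b, 1)
  c5 <- null_curve(0.5)
  expect_equal(c5$a, 1)
  expect_equal(c5$b, 2)
  # b - a = 1 for every p_c in [0, 1)
  for (p_c in seq(0, 0.99, by = 0.07)) {
    cv <- null_curve(p_c)
    expect_identical(cv$b - cv$a, 1)
  }
  expect_error(null_curve(1), "\\[0, 1\\)")
  expect_error(null_curve(-0.1), "\\[0, 1\\)")
})

test_that("expected consonant counts follow (m+1) p_c/(1-p_c)", {
  expect_equal(expected_consonants(0, 5), 0)
  expect_equal(expected_consonants(0.5, 1), 2)
  expect_equal(expected_consonants(0.48, 4), 5 * 0.48 / 0.52)
  expect_error(expected_consonants(0.3, -1), "non-negative")
})

test_that("null mean length is a/m + b, decreasing to the asymptote", {
  cv <- null_curve(0.48)
  y <- null_mean_length(cv, 1:50)
  expect_equal(y[1], cv$a + cv$b)
  expect_true(all(diff(y) < 0))
  expect_lt(y[50] - cv$b, 0.02)
  expect_equal(null_mean_length(null_curve(0), 1:10), rep(1, 10))
  expect_error(null_mean_length(cv, 0), ">= 1")
})

test_that("enumeration oracle matches the closed form on a parameter grid", {
  for (p_c in c(0, 0.15, 0.3, 0.48)) {
    for (p_v in c(0.2, 0.37, 0.5)) {
      if (p_c + p_v >= 1) next
      p <- source_params(p_c, p_v)
      cv <- null_curve(p_c)
      for (m in 1:5) {
        expect_equal(exact_conditional_mean(p, m, max_word_length = 80),
                     null_mean_length(cv, m), tolerance = 1e-6)
      }
    }
  }
})

test_that("the oracle agrees with literal string-by-string enumeration", {
  # every C/V string up to 14 graphemes, one arrangement at a time
  p_c <- 0.15
  p_v <- 0.15
  p_s <- 1 - p_c - p_v
  for (m_target in 1:2) {
    num <- 0
    den <- 0
    for (l in m_target:14) {
      ids <- 0:(2^l - 1)
      bits <- matrix(as.integer(intToBits(ids)), nrow = 32)[seq_len(l), ,
                                                            drop = FALSE]
      n_c <- colSums(bits)
      m <- l - n_c
      keep <- m == m_target
      w <- p_c^n_c[keep] * p_v^m[keep] * p_s
      num <- num + sum((l / m_target) * w)
      den <- den + sum(w)
    }
    expect_equal(num / den,
                 null_mean_length(null_curve(p_c), m_target),
                 tolerance = 1e-6)
  }
})

test_that("the oracle demands enough truncation mass", {
  p <- source_params(0.6, 0.3)
  expect_error(exact_conditional_mean(p, 3, max_word_length = 8),
               "increase max_word_length")
})

test_that("simulation is reproducible and matches nominal frequencies", {
  p <- source_params(0.48, 0.37)
  s1 <- simulate_symbols(p, 1e5, seed = 11)
  s2 <- simulate_symbols(p, 1e5, seed = 11)
  expect_identical(s1, s2)
  expect_false(identical(s1, simulate_symbols(p, 1e5, seed = 12)))
  freq <- table(factor(s1, levels = c("C", "V", "S"))) / 1e5
  nominal <- c(C = 0.48, V = 0.37, S = 0.15)
  se <- sqrt(nominal * (1 - nominal) / 1e5)
  expect_true(all(abs(freq - nominal) <= 3 * se))
  # degenerate limit: consonants dominate
  heavy <- simulate_symbols(source_params(0.98, 0.01), 1000, seed = 1)
  expect_gt(mean(heavy == "C"), 0.9)
})

test_that("segmentation records word compositions and cluster runs", {
  w <- segment_words(strsplit("CVSCVVS", "")[[1]])
  expect_equal(w$n, c(1L, 1L))
  expect_equal(w$m, c(1L, 2L))

  w2 <- segment_words(c("C", "C", "V", "C", "V", "S"))
  expect_equal(w2$n, 3L)
  expect_equal(w2$m, 2L)
  expect_equal(w2$clusters[[1]], c(2L, 1L, 0L))

  expect_equal(nrow(segment_words(c("S", "S"))), 0L)
  expect_error(segment_words(c("C", "X", "S")), "unknown symbol 'X'")
})

test_that("conditional means bin words by vowel count with a support filter", {
  words <- tibble::tibble(n = 2L, m = 1L)
  prof <- empirical_conditional_means(words, min_count = 1)
  expect_equal(prof$m, 1L)
  expect_equal(prof$mean_y, 3)
  expect_equal(nrow(empirical_conditional_means(words, min_count = 5)), 0L)
  # vowel-free words are excluded from the statistic
  mixed <- tibble::tibble(n = c(2L, 4L), m = c(1L, 0L))
  expect_equal(nrow(empirical_conditional_means(mixed, min_count = 1)), 1L)
})

test_that("simulated cluster lengths follow the geometric law", {
  # chi-square goodness of fit against P(N0 = n) = p_c^n (1 - p_c),
  # not rejected at alpha = 0.01 in at least 95% of seeded runs
  p_c <- 0.48
  p <- source_params(p_c, 0.37)
  seeds <- 1:20
  pass <- vapply(seeds, function(seed) {
    words <- segment_words(simulate_symbols(p, 1e5, seed = seed))
    # vowel-free maximal segments survive only when non-empty, which
    # truncates their first cluster; condition on m >= 1, under which the
    # leading cluster is exactly geometric
    words <- words[words$m >= 1, ]
    n0 <- vapply(words$clusters, `[`, integer(1), 1)
    k <- 8
    obs <- tabulate(pmin(n0, k) + 1L, nbins = k + 1L)
    probs <- c(p_c^(0:(k - 1)) * (1 - p_c), p_c^k)
    suppressWarnings(stats::chisq.test(obs, p = probs)$p.value) > 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("empirical conditional means track the exact curve", {
  p <- source_params(0.48, 0.37)
  words <- segment_words(simulate_symbols(p, 2e5, seed = 5),
                         clusters = FALSE)
  per_word <- dplyr::mutate(dplyr::filter(words, m >= 1),
                            y = (n + m) / m)
  prof <- empirical_conditional_means(words, min_count = 30)
  cv <- null_curve(0.48)
  for (i in seq_len(nrow(prof))) {
    sub <- per_word$y[per_word$m == prof$m[i]]
    se <- stats::sd(sub) / sqrt(length(sub))
    expect_lt(abs(prof$mean_y[i] - null_mean_length(cv, prof$m[i])),
              4 * se)
  }
})
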