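# Three-symbol memoryless ("monkey typing") source: i.i.d. emissions of
# C (consonant), V (vowel) and S (word delimiter) with probabilities
# p_c, p_v, p_s = 1 - p_c - p_v. Conditioning on a word containing m vowels,
# the mean syllable length (graphemes per vowel) is exactly a/m + b with
# a = p_c / (1 - p_c) and b = 1 + a.

#' Memoryless source parameters
#'
#' Emission probabilities of the three-symbol memoryless source. The
#' delimiter probability is derived as `p_s = 1 - p_c - p_v` and must be
#' strictly positive so that words terminate almost surely.
#'
#' @param p_c Probability of emitting a consonant symbol `C`.
#' @param p_v Probability of emitting a vowel symbol `V`.
#' @return An object of class `"source_params"` with elements `p_c`, `p_v`,
#'   `p_s`.
#' @examples
#' source_params(0.48, 0.37)
#' @export
source_params <- function(p_c, p_v) {
  stopifnot(is.numeric(p_c), is.numeric(p_v), length(p_c) == 1,
            length(p_v) == 1)
  if (p_c < 0 || p_v < 0 || p_c >= 1 || p_c + p_v >= 1) {
    abort("require p_c >= 0, p_v >= 0 and p_c + p_v < 1 (so p_s > 0)")
  }
  structure(
    list(p_c = p_c, p_v = p_v, p_s = 1 - p_c - p_v),
    class = "source_params"
  )
}

#' @export
print.source_params <- function(x, ...) {
  cat(sprintf(
    "memoryless source: p_c = %g, p_v = %g, p_s = %g\n", x$p_c, x$p_v, x$p_s
  ))
  invisible(x)
}

#' Exact Menzerath curve of the memoryless source
#'
#' Under the memoryless source the expected mean syllable length of a word
#' with `m` vowels is exactly `a/m + b`, with `a = p_c/(1 - p_c)` and
#' `b = 1 + a`. The curve depends on `p_c` alone, has a single degree of
#' freedom (`b - a = 1` always), is strictly decreasing in `m` whenever
#' `p_c > 0`, and decays to the asymptote `b` — a hyperbolic, not
#' exponential, approach, which is what separates this null model from the
#' Menzerath-Altmann law proper.
#'
#' @param p_c Consonant emission probability, in `[0, 1)`.
#' @return An object of class `"null_curve"`: list with elements `a` and `b`.
#' @examples
#' null_curve(0.48)  # a ~ 0.923, b ~ 1.923
#' @export
null_curve <- function(p_c) {
  stopifnot(is.numeric(p_c), length(p_c) == 1)
  if (p_c < 0 || p_c >= 1) {
    abort("p_c must lie in [0, 1)")
  }
  b <- 1 + p_c / (1 - p_c)
  # derive a from b so that b - a == 1 holds exactly in floating point
  structure(list(a = b - 1, b = b), class = "null_curve")
}

#' @export
print.null_curve <- function(x, ...) {
  cat(sprintf("null curve: E(y | m) = %g/m + %g\n", x$a, x$b))
  invisible(x)
}

#' Expected consonant count of a word with m vowels
#'
#' Consonant clusters of the memoryless source are i.i.d. geometric
#' (`P(N0 = n) = p_c^n (1 - p_c)`) and a word with `m` vowels has `m + 1` of
#' them, so `E(N | M = m) = (m + 1) p_c / (1 - p_c)`.
#'
#' @param p_c Consonant emission probability, in `[0, 1)`.
#' @param m Vowel (syllable) count, integer >= 0; vectorized.
#' @return Expected number of consonants.
#' @export
expected_consonants <- function(p_c, m) {
  if (p_c < 0 || p_c >= 1) {
    abort("p_c must lie in [0, 1)")
  }
  if (any(m < 0) || any(m != floor(m))) {
    abort("m must be a non-negative integer")
  }
  (m + 1) * p_c / (1 - p_c)
}

#' Evaluate the null curve a/m + b
#'
#' @param curve A `"null_curve"` object from [null_curve()].
#' @param m Syllable count, >= 1; vectorized.
#' @return Expected mean syllable length in graphemes.
#' @examples
#' null_mean_length(null_curve(0.48), 1:5)
#' @export
null_mean_length <- function(curve, m) {
  stopifnot(inherits(curve, "null_curve"))
  if (any(m < 1)) {
    abort("m must be >= 1 (mean syllable length is undefined without a vowel)")
  }
  curve$a / m + curve$b
}

#' Exact conditional mean syllable length by enumeration
#'
#' Independent verification oracle for the closed-form null curve: sums over
#' every C/V word up to `max_word_length` graphemes. All `choose(n + m, n)`
#' arrangements of `n` consonants and `m` vowels share the probability weight
#' `p_c^n * p_v^m * p_s`, so the enumeration reduces to an exact sum over
#' consonant counts. The truncated conditional mass (relative to the full
#' negative-binomial mass of the event `M = m`) must exceed `1 - 1e-8`,
#' otherwise an error asks for a larger bound.
#'
#' @param p A `"source_params"` object.
#' @param m Vowel count to condition on, integer >= 1.
#' @param max_word_length Truncation bound on word length in graphemes
#'   (default 60; the word-length tail is geometric with ratio `p_c + p_v`).
#' @return `E((N + M)/M | M = m)` under the truncation.
#' @export
exact_conditional_mean <- function(p, m, max_word_length = 60) {
  stopifnot(inherits(p, "source_params"))
  if (m < 1 || m != floor(m)) {
    abort("m must be an integer >= 1")
  }
  if (max_word_length < m) {
    abort("max_word_length must be at least m")
  }
  if (p$p_c == 0) {
    # only the all-vowel word contributes: (0 + m)/m
    return(1)
  }
  n <- 0:(max_word_length - m)
  log_w <- lchoose(n + m, n) + n * log(p$p_c) + m * log(p$p_v) + log(p$p_s)
  w <- exp(log_w)
  total_mass <- p$p_v^m * p$p_s / (1 - p$p_c)^(m + 1)
  if (sum(w) / total_mass < 1 - 1e-8) {
    abort(paste0(
      "truncated conditional mass below 1 - 1e-8; ",
      "increase max_word_length beyond ", max_word_length
    ))
  }
  sum((n + m) / m * w) / sum(w)
}

#' Simulate the memoryless source
#'
#' Draws `length` i.i.d. symbols over `{C, V, S}` with the probabilities of
#' `p`. The seed is a required argument so every simulation is reproducible.
#'
#' @param p A `"source_params"` object.
#' @param length Number of symbols to emit, >= 1.
#' @param seed Integer RNG seed.
#' @return Character vector of symbols.
#' @examples
#' simulate_symbols(source_params(0.48, 0.37), 20, seed = 1)
#' @export
simulate_symbols <- function(p, length, seed) {
  stopifnot(inherits(p, "source_params"), length >= 1)
  withr::with_seed(seed, sim_symbols_impl(p, length))
}

sim_symbols_impl <- function(p, length) {
  sample(c("C", "V", "S"), length, replace = TRUE,
         prob = c(p$p_c, p$p_v, p$p_s))
}

#' Segment a symbol stream into word compositions
#'
#' Words are the maximal `S`-free segments of the stream; empty segments
#' (consecutive delimiters) are dropped. For each word the consonant count
#' `n`, vowel count `m` and the consonant cluster lengths are recorded: a
#' word with `m` vowels has exactly `m + 1` clusters, cluster 0 preceding
#' the first vowel.
#'
#' @param stream Character vector over `{C, V, S}` (or a single collapsed
#'   string).
#' @param clusters If `TRUE` (default), include the per-word cluster lengths
#'   as a list-column; set `FALSE` to skip for large simulations.
#' @return A tibble with columns `n`, `m` and (optionally) `clusters`.
#' @examples
#' segment_words(c("C", "C", "V", "C", "V", "S"))  # n = 3, m = 2
#' @export
segment_words <- function(stream, clusters = TRUE) {
  if (length(stream) > 1) {
    stream <- paste(stream, collapse = "")
  }
  bad <- stringi::stri_replace_all_regex(stream, "[CVS]", "")
  if (nchar(bad) > 0) {
    abort(sprintf(
      "unknown symbol '%s' in stream (expected C, V or S)",
      substr(bad, 1, 1)
    ))
  }
  words <- stringi::stri_split_regex(stream, "S+", omit_empty = TRUE)[[1]]
  if (length(words) == 0) {
    out <- tibble(n = integer(0), m = integer(0))
    if (clusters) out$clusters <- list()
    return(out)
  }
  g <- stringi::stri_length(words)
  m <- g - stringi::stri_count_fixed(words, "C")
  out <- tibble(n = g - m, m = m)
  if (clusters) {
    pieces <- stringi::stri_split_fixed(words, "V")
    out$clusters <- map2(pieces, m, function(p, mm) {
      cl <- stringi::stri_length(p)
      # stri_split keeps empties, giving exactly m + 1 pieces
      length(cl) <- mm + 1L
      cl[is.na(cl)] <- 0L
      cl
    })
  }
  out
}

#' Empirical conditional mean syllable lengths
#'
#' Bins segmented words by vowel count `m` and reports the mean of
#' `(n + m)/m` per bin, the empirical counterpart of the null curve. Words
#' with `m = 0` are excluded (the statistic is undefined without a vowel)
#' and bins supported by fewer than `min_count` words are dropped.
#'
#' @param words Tibble with columns `n` and `m`, as from [segment_words()].
#' @param min_count Minimum words per `m` bin (default 10, the simulation
#'   threshold; corpus analyses conventionally use 25).
#' @return A length profile tibble: columns `m`, `mean_y`, `count`.
#' @export
empirical_conditional_means <- function(words, min_count = 10) {
  stopifnot(min_count >= 1)
  words |>
    filter(.data$m >= 1) |>
    group_by(m = .data$m) |>
    summarise(
      mean_y = mean((.data$n + .data$m) / .data$m),
      count = dplyr::n(),
      .groups = "drop"
    ) |>
    filter(.data$count >= min_count) |>
    arrange(.data$m) |>
    new_length_profile()
}

new_length_profile <- function(x) {
  structure(as_tibble(x), class = c("menz_profile", class(as_tibble(x))))
}
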