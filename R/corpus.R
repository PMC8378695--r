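# Corpus pipeline: tokenization, grapheme filtering, per-word measurement,
# the two aggregation methods (pooled corpus vs per-document averaging),
# corpus summary statistics and the Menzerath rank-correlation test.

default_delimiters <- c(
  ".", ",", ";", ":", "!", "?", "\"", "(", ")",
  "—", "–", "-", "'", "’",
  "«", "»", "“", "”",
  as.character(0:9)
)

#' Tokenize a document
#'
#' Lowercases and NFC-normalizes the text, then splits it into maximal runs
#' of non-delimiter characters. Delimiters are whitespace plus a configurable
#' punctuation-and-digit set; apostrophes and hyphens are delimiters by
#' default, so "end—start" tokenizes as two words.
#'
#' @param text A single document string (UTF-8).
#' @param delimiters Character vector of single-character delimiters added to
#'   whitespace.
#' @return Character vector of tokens (possibly empty).
#' @examples
#' tokenize("Two words.")
#' @export
tokenize <- function(text, delimiters = default_delimiters) {
  stopifnot(is.character(text), length(text) == 1)
  text <- stringi::stri_trans_nfc(stringi::stri_trans_tolower(text))
  cls <- paste0(
    "[\\s",
    paste0(vapply(delimiters, escape_for_class, character(1)), collapse = ""),
    "]+"
  )
  stringi::stri_split_regex(text, cls, omit_empty = TRUE)[[1]]
}

escape_for_class <- function(ch) {
  if (ch %in% c("\\", "^", "]", "-", "[", "&")) paste0("\\", ch) else ch
}

#' Filter tokens to the sonority-table alphabet
#'
#' A token survives iff every one of its graphemes appears in the sonority
#' table; the exclusion tally is returned for reporting (on curated corpora
#' the excluded fraction is typically far below 1%).
#'
#' @param tokens Character vector of lowercased tokens.
#' @param table Sonority table.
#' @return A list with elements `tokens` (kept) and `n_excluded`.
#' @export
filter_tokens <- function(tokens, table = sonority_table()) {
  mask <- vc_mask(tokens, table)
  keep <- !stringi::stri_detect_fixed(mask, "?")
  list(tokens = tokens[keep], n_excluded = sum(!keep))
}

#' Measure words: syllable count, grapheme count, mean syllable length
#'
#' For each token, the syllable count `m` (vowel runs), the grapheme count
#' `g` and the mean syllable length `y = g/m` in graphemes per syllable —
#' the construct-size / constituent-size pair the Menzerath-Altmann analysis
#' rests on. Vowel-free tokens (no rank-7 grapheme) are dropped by default.
#'
#' @param tokens Filtered, lowercased tokens.
#' @param table Sonority table.
#' @param exclude_vowel_free Drop tokens without a vowel (default `TRUE`).
#' @param doc Optional document id attached to every row.
#' @return A tibble with columns `word`, `m`, `g`, `y` and (if given) `doc`.
#' @examples
#' measure_words(c("barco", "a"))
#' @export
measure_words <- function(tokens, table = sonority_table(),
                          exclude_vowel_free = TRUE, doc = NULL) {
  tokens <- stringi::stri_trans_nfc(stringi::stri_trans_tolower(tokens))
  mask <- vc_mask(tokens, table)
  if (any(stringi::stri_detect_fixed(mask, "?"))) {
    bad <- tokens[stringi::stri_detect_fixed(mask, "?")][1]
    abort(sprintf("token '%s' contains graphemes absent from the table", bad))
  }
  n_runs <- stringi::stri_count_regex(mask, "V+")
  vowel_free <- n_runs == 0L
  out <- tibble(
    word = tokens,
    m = pmax(n_runs, 1L),
    g = stringi::stri_length(tokens)
  )
  out$y <- out$g / out$m
  if (!is.null(doc)) {
    out$doc <- doc
  }
  if (exclude_vowel_free) {
    out <- out[!vowel_free, ]
  }
  out
}

#' Length profile of the pooled corpus
#'
#' Aggregation method (i): all word tokens across all documents are pooled
#' into a single text and the mean syllable length is computed per word
#' length `m`. Bins supported by fewer than `min_count` tokens are dropped
#' (default 25); monosyllables are excluded by default since one-part
#' constructs frequently fail the law.
#'
#' @param measurements Tibble from [measure_words()] (rows from all
#'   documents).
#' @param min_count Minimum pooled token count per bin (default 25).
#' @param include_monosyllables Keep the `m = 1` bin (default `FALSE`).
#' @return A length profile tibble: `m`, `mean_y`, `count`.
#' @export
profile_full_corpus <- function(measurements, min_count = 25,
                                include_monosyllables = FALSE) {
  stopifnot(min_count >= 1)
  out <- measurements |>
    group_by(m = .data$m) |>
    summarise(mean_y = mean(.data$y), count = dplyr::n(), .groups = "drop")
  if (!include_monosyllables) {
    out <- filter(out, .data$m >= 2)
  }
  out |>
    filter(.data$count >= min_count) |>
    arrange(.data$m) |>
    new_length_profile()
}

#' Length profile by per-document averaging
#'
#' Aggregation method (ii): the mean syllable length is computed per document
#' and per word length `m`, then averaged (unweighted) across the documents
#' possessing that bin. The `min_count` filter applies to the pooled token
#' count per bin, so both methods retain the same set of `m` values. In the
#' canonical two-book example (one hundred 1-grapheme monosyllables in book
#' one, a single 2-grapheme monosyllable in book two) this method gives 1.5
#' graphemes at `m = 1` where pooling gives roughly 1.01.
#'
#' @param measurements Tibble from [measure_words()] with a `doc` column.
#' @inheritParams profile_full_corpus
#' @return A length profile tibble: `m`, `mean_y`, `count` (pooled count).
#' @export
profile_by_document <- function(measurements, min_count = 25,
                                include_monosyllables = FALSE) {
  stopifnot(min_count >= 1, "doc" %in% names(measurements))
  out <- measurements |>
    group_by(doc = .data$doc, m = .data$m) |>
    summarise(doc_mean = mean(.data$y), doc_count = dplyr::n(),
              .groups = "drop") |>
    group_by(m = .data$m) |>
    summarise(
      mean_y = mean(.data$doc_mean),
      count = sum(.data$doc_count),
      .groups = "drop"
    )
  if (!include_monosyllables) {
    out <- filter(out, .data$m >= 2)
  }
  out |>
    filter(.data$count >= min_count) |>
    arrange(.data$m) |>
    new_length_profile()
}

#' Corpus summary statistics
#'
#' Token, syllable, consonant and vowel totals plus the symbol probabilities
#' of the corpus viewed through the three-symbol alphabet: every grapheme of
#' every kept token is a `C` or `V`, and each inter-token gap counts as
#' exactly one `S` (the delimiter total is approximated by the token total).
#' The syllable-vowel ratio `Syll/V` gauges how well the one-vowel-nucleus
#' assumption of the memoryless source holds: it is 1 when every nucleus is
#' a single vowel and drops below 1 as diphthongs share nuclei.
#'
#' @param documents Character vector of document texts.
#' @param table Sonority table.
#' @param delimiters Tokenizer delimiter set.
#' @return A one-row tibble: `books`, `tokens`, `syllables`, `consonants`,
#'   `vowels`, `p_v`, `p_c`, `p_s`, `syll_v_ratio`, `n_excluded`.
#' @examples
#' corpus_summary("casa casa")
#' @export
corpus_summary <- function(documents, table = sonority_table(),
                           delimiters = default_delimiters) {
  tallies <- map(documents, function(text) {
    kept <- filter_tokens(tokenize(text, delimiters), table)
    meas <- measure_words(kept$tokens, table, exclude_vowel_free = FALSE)
    mask <- vc_mask(kept$tokens, table)
    list(
      tokens = length(kept$tokens),
      syllables = sum(meas$m),
      consonants = sum(stringi::stri_count_fixed(mask, "C")),
      vowels = sum(stringi::stri_count_fixed(mask, "V")),
      n_excluded = kept$n_excluded
    )
  })
  tot <- function(f) sum(map_dbl(tallies, f))
  tokens <- tot("tokens")
  consonants <- tot("consonants")
  vowels <- tot("vowels")
  symbols <- consonants + vowels + tokens
  tibble(
    books = length(documents),
    tokens = tokens,
    syllables = tot("syllables"),
    consonants = consonants,
    vowels = vowels,
    p_v = if (symbols > 0) vowels / symbols else NA_real_,
    p_c = if (symbols > 0) consonants / symbols else NA_real_,
    p_s = if (symbols > 0) tokens / symbols else NA_real_,
    syll_v_ratio = if (vowels > 0) tot("syllables") / vowels else NA_real_,
    n_excluded = tot("n_excluded")
  )
}

#' Spearman rank-correlation test of Menzerath's law
#'
#' Tests for a monotonic relation between word length `m` and mean syllable
#' length over the bins of a length profile. A strictly decreasing profile —
#' such as the exact null curve `a/m + b` — gives rho exactly -1. The exact
#' permutation distribution is used for 10 or fewer bins (the regime of
#' corpus profiles after the 25-count filter), the asymptotic approximation
#' otherwise; ties use midranks, and a constant profile is reported as
#' rho = 0, p = 1.
#'
#' @param profile Length profile tibble (`m`, `mean_y`), >= 3 bins.
#' @return A one-row tibble: `rho`, `p_value`, `n_bins`.
#' @examples
#' prof <- tibble::tibble(m = 2:8, mean_y = 1 / (2:8) + 2)
#' spearman_menzerath(prof)
#' @export
spearman_menzerath <- function(profile) {
  n <- nrow(profile)
  if (n < 3) {
    abort("correlation requires at least 3 profile bins")
  }
  if (sd(profile$mean_y) == 0 || sd(profile$m) == 0) {
    return(tibble(rho = 0, p_value = 1, n_bins = n))
  }
  has_ties <- anyDuplicated(profile$mean_y) > 0 ||
    anyDuplicated(profile$m) > 0
  use_exact <- n <= 10 && !has_ties
  ct <- suppressWarnings(
    cor.test(profile$m, profile$mean_y, method = "spearman",
             exact = use_exact)
  )
  # without ties, compute rho from the integer rank-difference sum so that
  # perfect monotonicity yields exactly +/-1 in floating point
  rho <- if (has_ties) {
    unname(ct$estimate)
  } else {
    s <- sum((rank(profile$m) - rank(profile$mean_y))^2)
    1 - 6 * s / (n * (n^2 - 1))
  }
  tibble(rho = rho, p_value = ct$p.value, n_bins = n)
}
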