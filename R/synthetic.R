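# Seeded synthetic-corpus generators. Every test input the package needs is
# generated in code: memoryless text rendered as real graphemes, words with
# known sonority-legal syllable boundaries, length profiles lying on a known
# Menzerath-Altmann curve, and corpora with position-dependent syllable
# structure. All generators are pure functions of (parameters, seed).

#' Render memoryless-source output as real graphemes
#'
#' Draws a C/V/S symbol stream from the memoryless source and renders it as
#' text: each `C` becomes a uniformly random consonant grapheme (sonority
#' ranks 1-6), each `V` a uniformly random vowel grapheme (rank 7), each `S`
#' a space. Rendering is uniform within class because the null model is
#' defined on symbol classes only — grapheme identities cannot affect any
#' class-level statistic. Both the rendered text and the underlying stream
#' are returned so pipeline and null-model segmentations can be compared
#' exactly.
#'
#' @param p A `"source_params"` object.
#' @param n_symbols Number of symbols to emit.
#' @param seed Integer RNG seed.
#' @param table Sonority table supplying the grapheme inventories.
#' @return A list with elements `text` (single string) and `symbols`
#'   (character vector over C/V/S).
#' @export
render_memoryless_text <- function(p, n_symbols, seed,
                                   table = sonority_table()) {
  stopifnot(inherits(p, "source_params"))
  vowels <- table$grapheme[table$rank == 7L]
  consonants <- table$grapheme[table$rank < 7L]
  if (length(vowels) == 0 || length(consonants) == 0) {
    abort("table must contain both vowel and consonant graphemes")
  }
  withr::with_seed(seed, {
    syms <- sim_symbols_impl(p, n_symbols)
    chars <- character(n_symbols)
    chars[syms == "S"] <- " "
    n_c <- sum(syms == "C")
    n_v <- sum(syms == "V")
    chars[syms == "C"] <- sample(consonants, n_c, replace = TRUE)
    chars[syms == "V"] <- sample(vowels, n_v, replace = TRUE)
    list(text = paste(chars, collapse = ""), symbols = syms)
  })
}

#' Generate sonority-legal words with known syllable boundaries
#'
#' Builds words syllable by syllable: an optional onset with strictly
#' increasing sonority, a single-vowel nucleus, and an optional coda with
#' strictly decreasing sonority drawn from ranks 2-6. Every non-initial
#' syllable starts with a rank-1 (occlusive) onset grapheme, so the
#' consonant cluster between two nuclei attains its sonority minimum
#' uniquely at the true boundary's right side — by construction the
#' syllabifier's split rule recovers the generating boundaries exactly.
#'
#' @param n_words Number of words.
#' @param seed Integer RNG seed.
#' @param max_syllables Maximum syllables per word (uniform 1..max).
#' @param table Sonority table.
#' @return A tibble: `word`, `m`, `boundaries` (list of 0-based split
#'   offsets), `syllables` (list of character vectors).
#' @export
generate_ssp_words <- function(n_words, seed, max_syllables = 4,
                               table = sonority_table()) {
  stopifnot(n_words >= 1, max_syllables >= 1)
  pools <- rank_pools(table)
  withr::with_seed(seed, {
    ms <- sample.int(max_syllables, n_words, replace = TRUE)
    sylls <- map(ms, function(m) {
      vapply(seq_len(m), function(i) {
        onset_len <- if (i == 1) sample(0:2, 1) else sample(1:2, 1)
        coda_len <- sample(0:2, 1)
        build_syllable(i, onset_len, coda_len, pools)
      }, character(1))
    })
    tibble(
      word = map_chr(sylls, paste, collapse = ""),
      m = ms,
      boundaries = map(sylls, function(s) {
        if (length(s) < 2) integer(0) else cumsum(nchar(head(s, -1)))
      }),
      syllables = sylls
    )
  })
}

# grapheme pools per sonority rank
rank_pools <- function(table) {
  pools <- split(table$grapheme, table$rank)
  if (!all(as.character(1:7) %in% names(pools))) {
    abort("table must provide at least one grapheme in every sonority rank")
  }
  pools
}

# one syllable: onset ranks strictly increasing (non-initial syllables are
# anchored at rank 1), single rank-7 nucleus, coda ranks strictly decreasing
# within 2..6
build_syllable <- function(i, onset_len, coda_len, pools) {
  onset_ranks <- integer(0)
  if (onset_len > 0) {
    if (i == 1) {
      onset_ranks <- sort(sample(1:6, onset_len))
    } else {
      extra <- if (onset_len > 1) sort(sample(2:6, onset_len - 1)) else NULL
      onset_ranks <- c(1L, extra)
    }
  }
  coda_ranks <- if (coda_len > 0) {
    sort(sample(2:6, coda_len), decreasing = TRUE)
  } else {
    integer(0)
  }
  ranks <- c(onset_ranks, 7L, coda_ranks)
  paste(vapply(as.character(ranks), function(r) {
    pool <- pools[[r]]
    pool[sample.int(length(pool), 1)]
  }, character(1)), collapse = "")
}

#' Generate a length profile on a known Menzerath-Altmann curve
#'
#' Produces per-length mean syllable sizes lying on
#' `mal_curve(m, alpha, beta, gamma)` with optional multiplicative Gaussian
#' noise, `mean_y = curve * (1 + eps)` with `eps ~ N(0, noise_sd)`, floored
#' at 0.01 so values stay positive. The fit-recovery harness for
#' [fit_mal()].
#'
#' @param alpha,beta,gamma Curve parameters.
#' @param m_range Integer vector of `m` bins.
#' @param count Supporting token count recorded per bin (single value or
#'   vector).
#' @param noise_sd Multiplicative noise standard deviation (0 = noiseless).
#' @param seed Integer RNG seed.
#' @return A length profile tibble: `m`, `mean_y`, `count`.
#' @export
generate_mal_profile <- function(alpha, beta, gamma, m_range = 2:12,
                                 count = 1000, noise_sd = 0, seed = 1) {
  stopifnot(noise_sd >= 0)
  y <- mal_curve(m_range, alpha, beta, gamma)
  eps <- if (noise_sd > 0) {
    withr::with_seed(seed, rnorm(length(m_range), 0, noise_sd))
  } else {
    rep(0, length(m_range))
  }
  new_length_profile(tibble(
    m = as.integer(m_range),
    mean_y = pmax(y * (1 + eps), 0.01),
    count = rep_len(count, length(m_range))
  ))
}

#' Default position-dependent syllable structure
#'
#' A qualitative stand-in for the positional regularity seen in natural
#' language: syllable length peaks at the second syllable and dips at the
#' penultimate one. `m_probs` is the word-length distribution; `g(i, m)` the
#' target mean grapheme length of syllable `i` in an `m`-syllable word
#' (>= 1, and >= 2 for non-initial syllables, whose onset is mandatory).
#'
#' @return A list with elements `m_probs` (named probability vector over
#'   `m`) and `g` (a `function(i, m)`).
#' @export
default_position_structure <- function() {
  list(
    m_probs = c(`1` = 0.20, `2` = 0.25, `3` = 0.22, `4` = 0.18,
                `5` = 0.10, `6` = 0.05),
    g = function(i, m) {
      if (m == 1) {
        return(3.0)
      }
      v <- 3.0
      if (i == 2) v <- 3.8
      if (m >= 4 && i == m - 1) v <- 2.4
      if (i == m && !(m >= 4 && i == m - 1)) v <- 3.2
      v
    }
  )
}

#' Generate a corpus with position-dependent syllable lengths
#'
#' Assembles words from sonority-legal syllables whose grapheme counts are
#' drawn around the target means `g(i, m)` of `structure`: syllable lengths
#' are shifted Poisson counts (`1 + Poisson(g - 1)` for initial syllables,
#' `2 + Poisson(g - 2)` for non-initial ones, capped at 12, the maximum
#' sonority-legal syllable length), so generated lengths are valid grapheme
#' counts with mean `g(i, m)` up to a negligible cap correction. The output
#' text is consumable by the full corpus pipeline, and the drawn per-word
#' syllable lengths are returned as ground truth.
#'
#' @param n_words Number of words.
#' @param seed Integer RNG seed.
#' @param structure A structure list as from [default_position_structure()].
#' @param table Sonority table.
#' @return A list with elements `text` (single space-separated string) and
#'   `words` (tibble: `word`, `m`, `syllable_lengths` list-column).
#' @export
generate_position_structured_corpus <- function(n_words, seed,
                                                structure =
                                                  default_position_structure(),
                                                table = sonority_table()) {
  stopifnot(n_words >= 1)
  probs <- structure$m_probs
  if (abs(sum(probs) - 1) > 1e-8) {
    abort("structure$m_probs must sum to 1")
  }
  g_fun <- structure$g
  pools <- rank_pools(table)
  withr::with_seed(seed, {
    ms <- sample(as.integer(names(probs)), n_words, replace = TRUE,
                 prob = probs)
    words <- map(ms, function(m) {
      lens <- vapply(seq_len(m), function(i) {
        g <- g_fun(i, m)
        # cap at 11 graphemes, the longest syllable both the onset
        # (<= 5 rising ranks + anchor/nucleus) and coda (<= 5 falling
        # ranks) constraints can realize
        if (i == 1) {
          if (g < 1) abort("g(i, m) must be >= 1")
          min(1L + rpois(1, g - 1), 11L)
        } else {
          if (g < 2) abort("g(i, m) must be >= 2 for non-initial syllables")
          min(2L + rpois(1, g - 2), 11L)
        }
      }, integer(1))
      sylls <- vapply(seq_len(m), function(i) {
        syllable_of_length(i, lens[i], pools)
      }, character(1))
      list(word = paste(sylls, collapse = ""), lengths = lens)
    })
    tbl <- tibble(
      word = map_chr(words, "word"),
      m = ms,
      syllable_lengths = map(words, "lengths")
    )
    list(text = paste(tbl$word, collapse = " "), words = tbl)
  })
}

# a sonority-legal syllable of exactly `len` graphemes; non-initial
# syllables (i > 1) have a mandatory rank-1 onset anchor
syllable_of_length <- function(i, len, pools) {
  extra <- len - 1L  # graphemes besides the nucleus
  if (i > 1) {
    extra <- extra - 1L  # the mandatory onset anchor
    if (extra < 0) abort("non-initial syllables need length >= 2")
  }
  max_onset_ext <- 5L  # strictly increasing within ranks 2..6
  max_coda <- 5L       # strictly decreasing within ranks 6..2
  onset_ext <- if (extra > 0) {
    lo <- max(0L, extra - max_coda)
    hi <- min(max_onset_ext, extra)
    if (lo == hi) lo else sample(lo:hi, 1)
  } else {
    0L
  }
  coda_len <- extra - onset_ext
  onset_ranks <- if (i == 1) {
    if (onset_ext > 0) sort(sample(1:6, onset_ext)) else integer(0)
  } else {
    c(1L, if (onset_ext > 0) sort(sample(2:6, onset_ext)) else NULL)
  }
  coda_ranks <- if (coda_len > 0) {
    sort(sample(2:6, coda_len), decreasing = TRUE)
  } else {
    integer(0)
  }
  ranks <- c(onset_ranks, 7L, coda_ranks)
  paste(vapply(as.character(ranks), function(r) {
    pool <- pools[[r]]
    pool[sample.int(length(pool), 1)]
  }, character(1)), collapse = "")
}
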