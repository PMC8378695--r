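# Sonority-sequencing syllabification.
#
# Nuclei are the maximal runs of rank-7 graphemes (so adjacent vowels share a
# syllable); each inter-nucleus consonant cluster is split immediately before
# the LAST grapheme attaining the cluster's minimum sonority, which places the
# sonority trough at a syllable onset ("bar-co", "gat-to", "as-tro").

#' Syllabify a word by the Sonority Sequencing Principle
#'
#' Splits a word into syllables using a seven-class sonority gradation.
#' Maximal runs of vowels (rank 7) form the nuclei; for every consonant
#' cluster between two nuclei the syllable boundary is placed immediately
#' before the last grapheme attaining the minimum sonority in the cluster, so
#' that sonority rises from the boundary towards the following nucleus.
#' Consonants before the first nucleus attach to the first syllable,
#' consonants after the last nucleus to the last. A word with no vowel at all
#' is returned as a single syllable with `vowel_free = TRUE`.
#'
#' @param word A single non-empty string (lowercased and NFC-normalized
#'   internally).
#' @param table Sonority table (default [sonority_table()]).
#' @return An object of class `"syllabified_word"`: a list with elements
#'   `word`, `syllables` (character vector), `boundaries` (integer offsets
#'   between graphemes, 0-based: boundary `k` splits after the `k`-th
#'   grapheme), `syllable_lengths` (grapheme counts) and `vowel_free`.
#' @examples
#' syllabify("barco")$syllables   # "bar" "co"
#' syllabify("aire")$syllables    # "ai" "re"
#' @export
syllabify <- function(word, table = sonority_table()) {
  stopifnot(is.character(word), length(word) == 1, nchar(word) > 0)
  word <- stringi::stri_trans_nfc(stringi::stri_trans_tolower(word))
  graphemes <- stringi::stri_split_boundaries(
    word, type = "character"
  )[[1]]
  lookup <- sonority_lookup(table)
  ranks <- unname(lookup[graphemes])
  if (anyNA(ranks)) {
    i <- which(is.na(ranks))[1]
    abort(sprintf(
      "unknown grapheme '%s' at position %d of '%s'", graphemes[i], i, word
    ))
  }
  boundaries <- ssp_boundaries(ranks)
  starts <- c(1L, boundaries + 1L)
  ends <- c(boundaries, length(ranks))
  syllables <- substring(word, starts, ends)
  structure(
    list(
      word = word,
      syllables = syllables,
      boundaries = boundaries,
      syllable_lengths = ends - starts + 1L,
      vowel_free = !any(ranks == 7L)
    ),
    class = "syllabified_word"
  )
}

# boundary offsets (0-based, split after that many graphemes) from ranks
ssp_boundaries <- function(ranks) {
  is_v <- ranks == 7L
  if (!any(is_v)) {
    return(integer(0))
  }
  r <- rle(is_v)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  v_runs <- which(r$values)
  if (length(v_runs) < 2) {
    return(integer(0))
  }
  # one boundary inside each cluster between consecutive nuclei
  vapply(seq_len(length(v_runs) - 1L), function(k) {
    cl_start <- run_end[v_runs[k]] + 1L
    cl_end <- run_start[v_runs[k + 1L]] - 1L
    cluster <- ranks[cl_start:cl_end]
    j <- max(which(cluster == min(cluster)))
    cl_start + j - 2L  # split after grapheme (cl_start + j - 2)
  }, integer(1))
}

#' @export
print.syllabified_word <- function(x, sep = "-", ...) {
  cat(paste(x$syllables, collapse = sep), "\n")
  invisible(x)
}

#' Syllabify a vector of words into a tidy table
#'
#' Vectorized companion to [syllabify()]: one row per word, with syllable
#' strings and grapheme lengths as list-columns.
#'
#' @param words Character vector of words.
#' @param table Sonority table.
#' @return A tibble with columns `word`, `m` (syllable count), `g` (grapheme
#'   count), `syllables` (list of character vectors), `syllable_lengths`
#'   (list of integer vectors) and `vowel_free` (logical).
#' @export
syllabify_words <- function(words, table = sonority_table()) {
  parsed <- map(words, syllabify, table = table)
  tibble(
    word = map_chr(parsed, "word"),
    m = map_int(parsed, ~ length(.x$syllables)),
    g = map_int(parsed, ~ sum(.x$syllable_lengths)),
    syllables = map(parsed, "syllables"),
    syllable_lengths = map(parsed, "syllable_lengths"),
    vowel_free = map_lgl(parsed, "vowel_free")
  )
}

#' Count syllables as vowel runs
#'
#' Fast vectorized syllable counting: the number of maximal runs of rank-7
#' (vowel) graphemes, or 1 for a vowel-free word. Agrees with
#' `length(syllabify(word)$syllables)` for every word.
#'
#' @param words Character vector of words (all graphemes must be in `table`).
#' @param table Sonority table.
#' @return Integer vector of syllable counts (>= 1).
#' @examples
#' syllable_count(c("idea", "aa", "grr"))  # 2 1 1
#' @export
syllable_count <- function(words, table = sonority_table()) {
  words <- stringi::stri_trans_nfc(stringi::stri_trans_tolower(words))
  mask <- vc_mask(words, table)
  if (any(stringi::stri_detect_fixed(mask, "?"))) {
    bad <- words[stringi::stri_detect_fixed(mask, "?")][1]
    abort(sprintf("word '%s' contains graphemes absent from the table", bad))
  }
  n_runs <- stringi::stri_count_regex(mask, "V+")
  pmax(n_runs, 1L)
}

# translate each character to V (vowel), C (consonant) or ? (absent)
vc_mask <- function(words, table) {
  old <- paste(table$grapheme, collapse = "")
  new <- paste(ifelse(table$rank == 7L, "V", "C"), collapse = "")
  translated <- chartr(old, new, words)
  # anything not translated to V/C was absent from the table
  stringi::stri_replace_all_regex(translated, "[^VC]", "?")
}

#' @importFrom purrr map_chr map_lgl
NULL
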