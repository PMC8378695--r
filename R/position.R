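# Positional syllable-length profiles: how the mean syllable length depends
# on the syllable's position within the word. The memoryless source predicts
# a flat profile (all consonant clusters equally long on average); natural
# language shows a maximum around the second syllable and a minimum around
# the penultimate one.

#' Standardized syllable position within a word
#'
#' Rescales the 1-based position `i` of a syllable in an `m`-syllable word
#' to `x = (i - 1)/(m - 1)` in `[0, 1]` (0 = first syllable, 1 = last);
#' monosyllables are placed at `x = 0.5`.
#'
#' @param i Syllable position, `1 <= i <= m`; vectorized.
#' @param m Word length in syllables; vectorized.
#' @return Standardized position in `[0, 1]`.
#' @examples
#' standardized_position(1:5, 5)
#' standardized_position(1, 1)  # 0.5
#' @export
standardized_position <- function(i, m) {
  if (any(i < 1) || any(i > m)) {
    abort("position i must satisfy 1 <= i <= m")
  }
  ifelse(m > 1, (i - 1) / (m - 1), 0.5)
}

#' Mean syllable length by word length and position
#'
#' Groups syllabified words by syllable count `m` and reports, for every
#' position `i = 1..m`, the mean grapheme length of the `i`-th syllable.
#' Every word of length `m` contributes exactly one syllable to each
#' position, so within an `m` group all positions share the same supporting
#' count. Monosyllables are retained (reported at `x = 0.5`); `m` groups
#' supported by fewer than `min_words_per_m` words are dropped.
#'
#' @param syllabified Tibble from [syllabify_words()] (columns `m` and
#'   `syllable_lengths`).
#' @param min_words_per_m Minimum words per `m` group (default 25).
#' @return A position profile tibble of class `"menz_positions"`: columns
#'   `m`, `i`, `x`, `mean_length`, `count`.
#' @examples
#' w <- syllabify_words(c("barco", "casa"))
#' positional_means(w, min_words_per_m = 1)
#' @export
positional_means <- function(syllabified, min_words_per_m = 25) {
  stopifnot(all(c("m", "syllable_lengths") %in% names(syllabified)))
  long <- syllabified |>
    select("m", "syllable_lengths") |>
    mutate(i = map(.data$syllable_lengths, seq_along)) |>
    tidyr::unnest(c("i", "syllable_lengths")) |>
    rename(len = "syllable_lengths")
  out <- long |>
    group_by(m = .data$m, i = .data$i) |>
    summarise(mean_length = mean(.data$len), count = dplyr::n(),
              .groups = "drop") |>
    filter(.data$count >= min_words_per_m) |>
    mutate(x = standardized_position(.data$i, .data$m)) |>
    select("m", "i", "x", "mean_length", "count") |>
    arrange(.data$m, .data$i)
  structure(out, class = c("menz_positions", class(out)))
}
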