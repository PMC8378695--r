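# Sonority classes, ranked from least sonorous (1) to most sonorous (7).
# The nucleus of a syllable is a sonority peak, so vowels sit at the top.
sonority_classes <- c(
  occlusive = 1L, affricate = 2L, fricative = 3L, nasal = 4L,
  liquid = 5L, approximant = 6L, vowel = 7L
)

# Default seven-class grapheme inventory covering common Latin-script
# alphabets (incl. accented vowels and special consonants like ß, þ, ð).
default_sonority_graphemes <- list(
  vowel = c(
    "a", "e", "i", "o", "u", "y", "à", "á", "â", "ä",
    "æ", "ã", "å", "ā", "ą", "è", "é",
    "ê", "ë", "ē", "ė", "ę", "î", "ï",
    "í", "ī", "į", "ì", "ô", "ö", "ò",
    "ó", "œ", "ø", "ō", "õ", "û", "ü",
    "ù", "ú", "ū", "ů", "ÿ", "ű", "ő",
    "ŵ", "ŷ", "ỳ", "ẁ", "ě", "ý", "ǫ"
  ),
  approximant = c("ŭ", "w", "ł"),
  liquid = c("l", "r", "ř"),
  nasal = c("m", "n", "ñ", "ń", "ŋ", "ň"),
  fricative = c(
    "ß", "z", "v", "s", "f", "ç", "ć", "ś", "ŝ",
    "ĉ", "ĥ", "h", "ĵ", "š", "ž", "ð", "đ"
  ),
  affricate = c("x", "j", "ź", "ż", "ĝ", "č"),
  occlusive = c(
    "b", "c", "d", "g", "t", "k", "p", "q", "þ", "ď", "ť"
  )
)

#' Grapheme sonority table
#'
#' The sonority table maps each grapheme (one Unicode code point, lowercase,
#' NFC-normalized) to one of seven sonority classes, ranked occlusives (1) <
#' affricates (2) < fricatives (3) < nasals (4) < liquids (5) < approximants
#' (6) < vowels (7). It drives both syllabification (sonority must rise
#' towards the nucleus and fall after it) and the three-way consonant /
#' vowel / space symbol classification used by the memoryless-source null
#' model. Each grapheme belongs to exactly one class — ambiguous graphemes
#' such as `y` or `w` are assigned their most frequent class.
#'
#' @return A tibble with columns `grapheme` (character), `class` (character,
#'   one of the seven class names) and `rank` (integer, 1-7).
#' @examples
#' tab <- sonority_table()
#' tab[tab$grapheme %in% c("a", "r", "t"), ]
#' @export
sonority_table <- function() {
  tab <- purrr::imap(default_sonority_graphemes, function(gs, cls) {
    tibble(grapheme = gs, class = cls, rank = sonority_classes[[cls]])
  })
  validate_sonority_table(dplyr::bind_rows(tab))
}

#' Read a sonority table from a two-column TSV file
#'
#' The file must have two tab-separated columns, `grapheme` and `class`
#' (header optional), with class names among the seven sonority classes
#' (singular or plural spelling, case-insensitive). Graphemes must be single
#' Unicode code points after NFC normalization and may not be repeated.
#'
#' @param path Path to a UTF-8 TSV file.
#' @return A validated sonority table tibble (see [sonority_table()]).
#' @export
read_sonority_table <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_names = c("grapheme", "class"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  # tolerate a header row
  if (nrow(raw) > 0 && tolower(raw$grapheme[1]) == "grapheme") {
    raw <- raw[-1, ]
  }
  cls <- normalize_class_name(raw$class)
  bad <- which(is.na(cls))
  if (length(bad) > 0) {
    abort(sprintf(
      "unknown sonority class '%s' at row %d of %s",
      raw$class[bad[1]], bad[1], path
    ))
  }
  validate_sonority_table(
    tibble(
      grapheme = stringi::stri_trans_nfc(
        stringi::stri_trans_tolower(raw$grapheme)
      ),
      class = cls,
      rank = unname(sonority_classes[cls])
    )
  )
}

#' Write a sonority table as two-column TSV
#'
#' @param table A sonority table tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sonority_table <- function(table, path) {
  table <- validate_sonority_table(table)
  readr::write_tsv(table[, c("grapheme", "class")], path, col_names = TRUE)
  invisible(path)
}

normalize_class_name <- function(x) {
  x <- sub("s$", "", tolower(trimws(x)))
  ifelse(x %in% names(sonority_classes), x, NA_character_)
}

validate_sonority_table <- function(table) {
  stopifnot(all(c("grapheme", "class", "rank") %in% names(table)))
  n_cp <- stringi::stri_length(table$grapheme)
  if (any(n_cp != 1L)) {
    i <- which(n_cp != 1L)[1]
    abort(sprintf(
      "grapheme '%s' (row %d) is not a single code point", table$grapheme[i], i
    ))
  }
  dup <- duplicated(table$grapheme)
  if (any(dup)) {
    i <- which(dup)[1]
    abort(sprintf(
      "duplicate grapheme '%s' (row %d)", table$grapheme[i], i
    ))
  }
  if (!all(table$rank %in% 1:7)) {
    abort("sonority ranks must lie in 1..7")
  }
  as_tibble(table)
}

# named integer lookup: grapheme -> rank
sonority_lookup <- function(table) {
  setNames(as.integer(table$rank), table$grapheme)
}

#' Classify characters as consonant, vowel or space symbols
#'
#' Collapses graphemes into the three symbol classes of the memoryless-source
#' null model: rank-7 graphemes (vowels) map to `"V"`, ranks 1-6 (all
#' consonant classes) map to `"C"`, and any character absent from the table —
#' whitespace, punctuation, digits — maps to the delimiter `"S"`. This is a
#' total function: no input character is an error.
#'
#' @param chars Character vector of single characters.
#' @param table Sonority table (default [sonority_table()]).
#' @return Character vector over `{"C", "V", "S"}` of the same length.
#' @examples
#' classify_symbols(c("o", "t", ",", " "))
#' @export
classify_symbols <- function(chars, table = sonority_table()) {
  rank <- unname(sonority_lookup(table)[chars])
  out <- ifelse(is.na(rank), "S", ifelse(rank == 7L, "V", "C"))
  out
}
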