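# shared fixtures built in code

default_table <- sonority_table()

# random words over the default alphabet (not necessarily sonority-legal)
random_table_words <- function(n, seed, min_len = 1, max_len = 10) {
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      len <- sample(min_len:max_len, 1)
      paste(sample(default_table$grapheme, len, replace = TRUE),
            collapse = "")
    }, character(1))
  })
}

# sonority rank sequence of a word
word_ranks <- function(word, table = default_table) {
  graphemes <- strsplit(word, "")[[1]]
  unname(sonority_lookup_test(table)[graphemes])
}

sonority_lookup_test <- function(table) {
  stats::setNames(as.integer(table$rank), table$grapheme)
}

# consonant/vowel counts of tokens via classify_symbols, an independent path
token_cv_counts <- function(tokens, table = default_table) {
  counts <- lapply(tokens, function(tok) {
    cls <- classify_symbols(strsplit(tok, "")[[1]], table)
    c(n = sum(cls == "C"), m = sum(cls == "V"))
  })
  list(
    n = vapply(counts, function(x) as.integer(x[["n"]]), integer(1)),
    m = vapply(counts, function(x) as.integer(x[["m"]]), integer(1))
  )
}
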