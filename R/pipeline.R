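# End-to-end runs: the memoryless-source validation experiment and the full
# corpus analysis bundle.

#' Run the memoryless-source validation experiment
#'
#' Simulates the three-symbol source, bins the empirical mean syllable
#' lengths by vowel count, and overlays the exact curve `a/m + b`. For each
#' retained bin the deviation from theory is reported in units of the bin's
#' standard error, the natural scale on which simulation and closed form
#' should agree.
#'
#' @param seed Integer RNG seed (required).
#' @param p_c,p_v Source emission probabilities (defaults 0.48 and 0.37,
#'   approximating consonant/vowel frequencies of natural language).
#' @param n_symbols Symbols to simulate (default `1e6`).
#' @param min_count Minimum words per bin (default 10).
#' @param out_dir Optional directory: writes `null_profile.csv` (per-bin
#'   table) and `null_summary.json`.
#' @return A list: `profile` (tibble `m`, `mean_y`, `count`, `theory`, `se`,
#'   `dev_se`), `curve` (the `"null_curve"`), and `summary` (tibble with
#'   `max_abs_dev_se`, `frac_within_3se`, `n_bins`).
#' @export
run_null_experiment <- function(seed, p_c = 0.48, p_v = 0.37,
                                n_symbols = 1e6, min_count = 10,
                                out_dir = NULL) {
  p <- source_params(p_c, p_v)
  curve <- null_curve(p_c)
  words <- segment_words(simulate_symbols(p, n_symbols, seed),
                         clusters = FALSE)
  per_word <- words |>
    filter(.data$m >= 1) |>
    mutate(y = (.data$n + .data$m) / .data$m)
  profile <- per_word |>
    group_by(m = .data$m) |>
    summarise(
      mean_y = mean(.data$y),
      count = dplyr::n(),
      se = sd(.data$y) / sqrt(dplyr::n()),
      .groups = "drop"
    ) |>
    filter(.data$count >= min_count) |>
    arrange(.data$m) |>
    mutate(
      theory = null_mean_length(curve, .data$m),
      dev_se = ifelse(.data$se > 0,
                      (.data$mean_y - .data$theory) / .data$se, 0)
    )
  summary <- tibble(
    max_abs_dev_se = max(abs(profile$dev_se)),
    frac_within_3se = mean(abs(profile$dev_se) <= 3),
    n_bins = nrow(profile)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(profile, file.path(out_dir, "null_profile.csv"))
    jsonlite::write_json(
      c(as.list(summary), list(a = curve$a, b = curve$b, seed = seed,
                               n_symbols = n_symbols)),
      file.path(out_dir, "null_summary.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  list(profile = profile, curve = curve, summary = summary)
}

#' Run the full corpus analysis
#'
#' Tokenizes, filters and measures every document, then produces the whole
#' analysis bundle: corpus summary, pooled and per-document length profiles,
#' the Spearman correlation test, the Menzerath-Altmann fit (on the
#' per-document profile, the aggregation the analysis standardizes on), the
#' positional syllable-length profile, and a log of every exclusion tally.
#'
#' @param documents Character vector of document texts, or the path of a
#'   directory of UTF-8 `.txt` files (one document each).
#' @param table Sonority table.
#' @param min_count Minimum pooled token count per length bin (default 25).
#' @param include_monosyllables Keep `m = 1` bins in length profiles
#'   (default `FALSE`).
#' @param exclude_vowel_free Drop vowel-free tokens (default `TRUE`).
#' @param delimiters Tokenizer delimiter set.
#' @param out_dir Optional directory to write `summary.json`,
#'   `profile_pooled.csv`, `profile_by_document.csv`, `correlation.json`,
#'   `mal_fit.json`, `positions.csv` and `run_log.json`.
#' @return A list of class `"menz_analysis"`: `summary`, `profile_pooled`,
#'   `profile_by_document`, `correlation`, `fit`, `positions`, `log`.
#' @export
run_corpus_analysis <- function(documents, table = sonority_table(),
                                min_count = 25,
                                include_monosyllables = FALSE,
                                exclude_vowel_free = TRUE,
                                delimiters = default_delimiters,
                                out_dir = NULL) {
  is_dir_input <- length(documents) == 1 && !is.na(documents) &&
    nchar(documents) < 500 && !grepl("\n", documents, fixed = TRUE) &&
    dir.exists(documents)
  if (is_dir_input) {
    paths <- list.files(documents, pattern = "\\.txt$", full.names = TRUE)
    if (length(paths) == 0) {
      abort(sprintf("no .txt documents found in '%s'", documents))
    }
    documents <- setNames(
      map_chr(paths, ~ paste(readr::read_lines(.x), collapse = "\n")),
      basename(paths)
    )
  }
  if (is.null(names(documents))) {
    names(documents) <- sprintf("doc%03d", seq_along(documents))
  }

  kept <- map(documents, ~ filter_tokens(tokenize(.x, delimiters), table))
  measurements <- dplyr::bind_rows(purrr::imap(
    kept, ~ measure_words(.x$tokens, table,
                          exclude_vowel_free = exclude_vowel_free,
                          doc = .y)
  ))
  if (nrow(measurements) == 0) {
    abort("no usable word tokens in the corpus")
  }

  profile_pooled <- profile_full_corpus(measurements, min_count,
                                        include_monosyllables)
  profile_by_doc <- profile_by_document(measurements, min_count,
                                        include_monosyllables)
  correlation <- if (nrow(profile_by_doc) >= 3) {
    spearman_menzerath(profile_by_doc)
  } else {
    NULL
  }
  fit <- if (nrow(profile_by_doc) >= 4) fit_mal(profile_by_doc) else NULL

  syll <- syllabify_words(measurements$word, table)
  positions <- positional_means(syll, min_words_per_m = min_count)

  n_excluded <- sum(map_dbl(kept, "n_excluded"))
  n_tokens <- sum(map_dbl(kept, ~ length(.x$tokens))) + n_excluded
  log <- list(
    documents = length(documents),
    tokens_total = n_tokens,
    tokens_excluded_alphabet = n_excluded,
    excluded_fraction = if (n_tokens > 0) n_excluded / n_tokens else NA,
    tokens_measured = nrow(measurements),
    min_count = min_count,
    include_monosyllables = include_monosyllables,
    exclude_vowel_free = exclude_vowel_free
  )

  bundle <- structure(
    list(
      summary = corpus_summary(documents, table, delimiters),
      profile_pooled = profile_pooled,
      profile_by_document = profile_by_doc,
      correlation = correlation,
      fit = fit,
      positions = positions,
      log = log
    ),
    class = "menz_analysis"
  )
  if (!is.null(out_dir)) {
    write_analysis(bundle, out_dir)
  }
  bundle
}

write_analysis <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(as.list(bundle$summary),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(bundle$profile_pooled,
                   file.path(out_dir, "profile_pooled.csv"))
  readr::write_csv(bundle$profile_by_document,
                   file.path(out_dir, "profile_by_document.csv"))
  if (!is.null(bundle$correlation)) {
    jsonlite::write_json(as.list(bundle$correlation),
                         file.path(out_dir, "correlation.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(bundle$fit)) {
    jsonlite::write_json(as.list(glance(bundle$fit)),
                         file.path(out_dir, "mal_fit.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  readr::write_csv(as_tibble(bundle$positions),
                   file.path(out_dir, "positions.csv"))
  jsonlite::write_json(bundle$log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.menz_analysis <- function(x, ...) {
  cat("Corpus analysis bundle\n")
  cat(sprintf("  documents: %d, measured tokens: %d (%.3g%% excluded)\n",
              x$log$documents, x$log$tokens_measured,
              100 * x$log$excluded_fraction))
  cat(sprintf("  length profile bins (by-document method): %d\n",
              nrow(x$profile_by_document)))
  if (!is.null(x$correlation)) {
    cat(sprintf("  Spearman rho = %.3f (p = %.3g)\n",
                x$correlation$rho, x$correlation$p_value))
  }
  if (!is.null(x$fit)) {
    print(x$fit)
  }
  invisible(x)
}
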