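# menzerath

Menzerath–Altmann law analysis for word/syllable/grapheme hierarchies, with
an exact memoryless-source null model.

## The problem

Across languages — and across hierarchies well beyond language, from
genomes to animal vocal sequences — longer constructs tend to have shorter
constituents: words with more syllables have, on average, shorter
syllables. Two distinct claims hide under that observation:

* **Menzerath's law** — a monotonic negative association between construct
  size *m* and mean constituent size *y*, usually tested by rank
  correlation;
* **the Menzerath–Altmann law (MAL)** — the parametric regression

  *y*(*m*) = α · *m*^β · exp(−γ·*m*),  α > 0,

  which, whenever β·γ > 0, has an extremum at *m*\* = β/γ beyond which
  constituents *grow* with construct size (the *inverted regime*).

The distinction matters because a trivial null model already satisfies the
first claim. A one-state source emitting consonant, vowel and delimiter
symbols i.i.d. with probabilities *p_c*, *p_v*, *p_s* yields an exact
conditional mean syllable length of

  E(*y* | *m*) = *a*/*m* + *b*,  *a* = *p_c*/(1 − *p_c*),  *b* = 1 + *a*,

a strictly decreasing hyperbola whose Spearman correlation with *m* is
exactly −1. Monotone shortening is therefore no evidence of communicative
complexity; the discriminating signatures are the exponential term of MAL,
its inverted regime, and position-dependent constituent structure — all of
which the null model provably lacks and this package measures.

The package is for quantitative linguists and anyone doing
construct/constituent statistics on sequence data: it provides the null
model (closed forms, an enumeration oracle, and seeded simulation), a
deterministic sonority-sequencing syllabifier over a seven-class grapheme
table, a corpus pipeline (tokenization, alphabet filtering, pooled and
per-document length profiles, Spearman testing), Levenberg–Marquardt MAL
fitting with extremum detection, positional syllable-length profiles, and
synthetic-corpus generators so every stage is testable without external
data.

## Worked example

Syllabify a word, analyze a synthetic corpus, and validate the null model:

```r
library(menzerath)

syllabify("barco")
#> bar-co

# a 3,000-word corpus with position-dependent syllable structure,
# split into three "books"
corp  <- generate_position_structured_corpus(3000, seed = 42)
words <- corp$words$word
docs  <- vapply(split(words, rep(1:3, length.out = length(words))),
                paste, character(1), collapse = " ")

bundle <- run_corpus_analysis(docs, min_count = 25)
bundle
#> Corpus analysis bundle
#>   documents: 3, measured tokens: 3000 (0% excluded)
#>   length profile bins (by-document method): 5
#>   Spearman rho = -0.800 (p = 0.133)
#> Menzerath-Altmann fit: y = alpha * m^beta * exp(-gamma m)
#>   alpha = 3.126, beta = 0.2215, gamma = 0.07039
#>   R^2 = 0.4509 on 5 bins; converged: TRUE
#>   extremum (inverted regime onset) at m* = beta/gamma = 3.1

bundle$profile_by_document
#> # A tibble: 5 x 3
#>       m mean_y count
#>   <int>  <dbl> <int>
#> 1     2   3.13   775
#> 2     3   3.34   637
#> 3     4   3.12   564
#> 4     5   3.12   296
#> 5     6   3.08   146
```

Reading the output: the five retained bins (word lengths 2–6 syllables,
each supported by at least 25 tokens) give the mean syllable length in
graphemes per word length, averaged per book and then across books. The
rank correlation is negative but not significant on five points, and the
fitted MAL parameters land in the β·γ > 0 regime with an extremum around
3 syllables — as expected, since this generator builds words around a
positional bump/dip structure rather than a monotone profile. The
positional profile itself is in `bundle$positions`
(`autoplot(bundle$positions)` plots it).

The null model, simulated and compared to its exact curve:

```r
res <- run_null_experiment(seed = 1, n_symbols = 1e5)
res$curve
#> null curve: E(y | m) = 0.923077/m + 1.92308
res$summary
#> # A tibble: 1 x 3
#>   max_abs_dev_se frac_within_3se n_bins
#>            <dbl>           <dbl>  <int>
#> 1           2.31               1     18
```

Every retained bin of a 100,000-symbol simulation at *p_c* = 0.48,
*p_v* = 0.37 sits within 3 standard errors of *a*/*m* + *b*.

Fitted MAL objects work with the usual verbs: `tidy(fit)`, `glance(fit)`,
`predict(fit, m)`, `autoplot(fit)`; `mal_extremum(beta, gamma)` gives the
inverted-regime onset β/γ when β·γ > 0.

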