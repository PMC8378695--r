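---
title: "Methods: the Menzerath-Altmann law, its memoryless null model, and how this package computes both"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Menzerath-Altmann law, its memoryless null model, and how this package computes both}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(menzerath)
library(dplyr)
```

## The two laws

Menzerath's law is the qualitative observation that longer linguistic
constructs tend to have shorter constituents: the more syllables a word
has, the fewer graphemes each syllable carries on average. The
Menzerath-Altmann law (MAL) sharpens this into a parametric regression for
the mean constituent size $y$ as a function of construct size $m$:

$$y(m) = \alpha\, m^{\beta} e^{-\gamma m}, \qquad \alpha > 0,$$

with $\beta$ and $\gamma$ typically negative for natural language. The two
statements are not equivalent. A correlation analysis (Menzerath's law)
only asks whether $y$ decreases monotonically with $m$; the MAL curve can
additionally possess an interior extremum at $m^\ast = \beta/\gamma$
whenever $\beta\gamma > 0$, beyond which syllables *grow* with word length
— the *inverted regime*. This package exists to compute both analyses, and
to compare them against a null model that satisfies the first law but can
never produce the second signature.

Throughout, the construct is the word token, the constituent is the
syllable, and sizes are measured in graphemes (single Unicode code points
after lowercasing and NFC normalization).

## The memoryless-source null model

The null model is a one-state source emitting i.i.d. symbols: consonant
$C$ with probability $p_c$, vowel $V$ with probability $p_v$, and delimiter
$S$ with probability $p_s = 1 - p_c - p_v$. Maximal $S$-free runs are
words; the number of syllables in a word is approximated by its number of
vowels $M$, and its length is $N + M$ where $N$ counts consonants.

Conditioned on $M = m$, the word consists of $m + 1$ consonant clusters
(one before each vowel and one trailing), each independently geometric,
$P(N_0 = n) = p_c^n(1 - p_c)$. Hence
$E(N \mid M = m) = (m+1)\,p_c/(1-p_c)$ and the exact conditional mean
syllable length is

$$E\!\left(\tfrac{N+M}{M}\,\middle|\,M = m\right) = \frac{a}{m} + b,
\qquad a = \frac{p_c}{1-p_c},\quad b = 1 + a.$$

This hyperbola is strictly decreasing for $p_c > 0$, so its Spearman
correlation with $m$ is exactly $-1$: the null model satisfies Menzerath's
law perfectly. It has a single degree of freedom ($b - a = 1$ always),
approaches its asymptote $b$ hyperbolically rather than exponentially, and
its conditional cluster lengths are position-independent — three properties
that natural language data violate and that the rest of the package is
built to measure.

`null_curve()`, `expected_consonants()` and `null_mean_length()` implement
the closed forms; `simulate_symbols()`, `segment_words()` and
`empirical_conditional_means()` implement the simulation route; and
`exact_conditional_mean()` is an independent enumeration oracle (below).
`run_null_experiment()` wires the simulation against the closed form and
reports per-bin deviations in standard-error units.

### Numerical choices in the null model

* **Exactness of $b - a = 1$.** `null_curve()` computes $b$ first and
  derives $a = b - 1$; both floating-point subtractions are exact by
  construction, so the invariant holds *identically*, not merely to
  rounding.
* **The enumeration oracle.** `exact_conditional_mean()` sums over every
  $C/V$ word up to a truncation length (default 60 graphemes). All
  $\binom{n+m}{n}$ arrangements of $n$ consonants and $m$ vowels carry the
  same weight $p_c^n p_v^m p_s$, so the string sum collapses to an exact
  sum over consonant counts; the test suite additionally cross-checks this
  against literal string-by-string enumeration at small lengths. The
  truncated conditional mass is compared against the full negative-binomial
  mass of $\{M = m\}$ and must exceed $1 - 10^{-8}$, otherwise the function
  refuses and asks for a larger bound. The word-length tail is geometric
  with ratio $p_c + p_v$, so the default bound is ample for realistic
  parameters.
* **Degenerate inputs.** $p_c = 0$ makes every syllable a lone vowel; the
  oracle returns 1 directly rather than evaluating $\log 0$. Words with
  $m = 0$ (no vowel) are excluded from the conditional statistic, which is
  undefined there; they still count in symbol totals. Empty inter-delimiter
  segments (consecutive $S$) are dropped silently. One subtlety the test
  suite documents: vowel-free maximal segments survive only when non-empty,
  which truncates *their* leading cluster; the geometric law for cluster
  lengths is therefore asserted conditional on $m \ge 1$, where it is
  exact.
* **Seeding.** Every stochastic operation takes a required integer seed and
  restores the caller's RNG state (`withr::with_seed`), so all simulations
  are pure functions of their arguments.

## Sonority-sequencing syllabification

Syllabification uses a seven-class sonority gradation — occlusives (1) <
affricates (2) < fricatives (3) < nasals (4) < liquids (5) < approximants
(6) < vowels (7) — over a fixed grapheme table covering Latin-script
alphabets (`sonority_table()`; loadable from TSV via
`read_sonority_table()`). Each grapheme belongs to exactly one class;
ambiguous letters such as `y` and `w` keep their most frequent class. The
table is strictly per-character: digraphs like `ch` or `ll` are not units.

The segmentation rule is deterministic:

1. **Nuclei** are the maximal runs of rank-7 graphemes, so adjacent vowels
   (diphthongs) share one syllable. This is why the syllable-to-vowel
   ratio of a corpus is at most 1.
2. For each consonant cluster between two nuclei, the boundary falls
   immediately **before the last grapheme attaining the cluster's minimum
   sonority**. Sonority therefore rises from each boundary towards the
   following nucleus: "barco" → *bar-co* (cluster ranks 5,1), "gatto" →
   *gat-to* (plateau 1,1 split before the second), "astro" → *as-tro*.
3. Word-initial consonants attach to the first syllable, word-final ones to
   the last. Vowel-free tokens are one syllable with a `vowel_free` flag; a
   pipeline option excludes them from statistics (the default).

The rule was fixed here deliberately — existing sonority-based tokenizers
do not publish a normative algorithm, and a reproducible, testable rule
matters more for the statistics than parity with any particular
implementation. One consequence worth knowing: onset legality (sonority
non-decreasing up to the nucleus) is guaranteed for sonority-*legal* words,
and the generator below produces only such words; arbitrary grapheme
strings can force illegal word-initial onsets (they attach to syllable one
unconditionally) or non-monotone onsets out of clusters like ranks
3-1-4-2, and the package keeps the concatenation invariant — syllables
always rejoin to the input — rather than pretending such strings have
well-formed syllables.

`classify_symbols()` collapses the same table to the null model's alphabet:
rank 7 → `V`, ranks 1–6 → `C`, anything outside the table (spaces,
punctuation, digits) → `S`.

## The corpus pipeline

`tokenize()` lowercases, NFC-normalizes and splits on whitespace plus a
configurable punctuation-and-digit set; apostrophes and hyphens are
delimiters by default, a choice made because intra-word punctuation
conventions vary by language and treating them as separators is the only
language-neutral option (it is configurable). `filter_tokens()` keeps only
tokens spelled entirely inside the sonority table and reports the excluded
tally. `measure_words()` produces per-token $(m, g, y = g/m)$.

Two aggregation methods produce the length profile $m \mapsto \bar y$:

* `profile_full_corpus()` pools all tokens as one text;
* `profile_by_document()` averages within each document first, then takes
  the unweighted mean across documents possessing the bin.

The two can differ: in the canonical two-book construction (one hundred
1-grapheme monosyllables in one book, a single 2-grapheme monosyllable in
the other) pooling gives $102/101 \approx 1.01$ while per-book averaging
gives $1.5$. The unweighted average-of-averages is what makes that example
come out at 1.5, and is the convention adopted here. Profile bins need at
least 25 supporting tokens by default (10 is the convention for null-model
simulations — the two thresholds are distinct and both configurable), and
monosyllables are excluded by default because one-part constructs
notoriously disobey the law; both switches are arguments. The 25-count
filter is applied to the *pooled* count per bin in both methods, so the two
profiles always retain the same bins and remain comparable bin-by-bin; the
per-document mean then averages the documents that contribute to the bin.

`spearman_menzerath()` tests monotonicity over profile bins. With 10 or
fewer bins — the usual situation after filtering — it uses the exact
distribution rather than the asymptotic approximation, since t-based
p-values are unreliable at $n \approx 7$–10. Ties use midranks; when there
are no ties the statistic is assembled from the integer rank-difference
sum, so perfectly monotone profiles return exactly $\pm 1$ in floating
point. A constant profile is reported as $\rho = 0$, $p = 1$ rather than
`NA`.

## Fitting the MAL curve

`fit_mal()` fits $\alpha m^\beta e^{-\gamma m}$ to the profile's
$(m, \bar y)$ points by Levenberg-Marquardt nonlinear least squares
(`minpack.lm::nlsLM`). Choices that matter:

* **Fit target.** The per-$m$ mean values, not raw tokens — the profile is
  the object the law is stated about. Unweighted by default;
  `weights = "counts"` is available when bins should count in proportion
  to their support.
* **Initialization.** $\alpha_0$ = the mean at the smallest fitted $m$,
  $\beta_0 = \gamma_0 = -0.05$. The model is log-linearizable but is fitted
  in linear space, which can be multi-modal; on non-convergence a 3×3
  multi-start grid over $\beta_0, \gamma_0 \in \{-0.2, -0.05, 0.05\}$ is
  tried and the converged fit with the smallest residual sum wins.
* **Goodness of fit.** $R^2 = 1 - SS_{res}/SS_{tot}$ on exactly the bins
  fitted (post-filter, post-monosyllable-exclusion). Zero-residual fits can
  terminate on the function-tolerance criterion without the convergence
  flag; residuals below $10^{-20}$ are treated as converged.
* **Extremum.** `mal_extremum()` returns $\beta/\gamma$ iff
  $\beta\gamma > 0$; the derivative of the curve vanishes there. Fits of
  the *null* curve $a/m + b$ over $m = 2..12$ are a cautionary example the
  test suite pins down: the least-squares optimum is
  $\beta \approx -0.18, \gamma \approx -0.015$ with $R^2 \approx 0.996$ —
  formally $\beta\gamma > 0$ — but the implied extremum sits at the upper
  edge of the fitted range and the rise beyond it is under 0.1% of the
  curve value. The meaningful statement is not a sign pattern but the
  absence of a *material* inverted regime, and that is what the tests
  assert.

## Positional profiles

`positional_means()` groups syllabified words by length $m$ and averages
the grapheme length of the $i$-th syllable. The position is standardized
as $x = (i-1)/(m-1)$, with monosyllables at $x = 0.5$; positions are
1-based internally and $x$ is derived output only, which avoids off-by-one
drift. Every word of length $m$ contributes one syllable to every
position, so all cells of an $m$ group share one count, and two exact
identities hold: summed positional means times the group count equals the
group's total grapheme count, and the equal-weight average of positional
means reproduces the length profile's $\bar y$ at that $m$. Monosyllables
are retained here (unlike in the length profile) because the positional
analysis is where their behaviour is interesting; the per-$m$ support
threshold defaults to the corpus convention of 25.

## Synthetic data: what it emulates and what it does not

All test inputs are generated in code, as pure functions of parameters and
seed:

* `render_memoryless_text()` draws the $C/V/S$ stream and renders it with
  uniformly random graphemes within each class. Uniformity is the minimal
  assumption — the null model is defined on classes, so grapheme identity
  cannot affect any class-level statistic — and returning the underlying
  stream lets the test suite verify that the corpus pipeline reproduces the
  null-model segmentation *exactly*, token by token.
* `generate_ssp_words()` builds words from sonority-legal syllables:
  strictly rising onsets, single-vowel nuclei, strictly falling codas
  within ranks 2–6, and every non-initial syllable anchored by a rank-1
  onset grapheme. That anchoring makes the inter-nucleus sonority minimum
  unique at the true boundary's right side, so the syllabifier recovers the
  generating boundaries with certainty — the round-trip is a deterministic
  oracle, and the acceptance suite checks it on $10^4$ words.
* `generate_mal_profile()` places profile points on a chosen MAL curve with
  multiplicative Gaussian noise, the harness for fit recovery.
* `generate_position_structured_corpus()` draws syllable lengths as shifted
  Poisson counts (support starts at 1, or at 2 for non-initial syllables,
  whose onset anchor is mandatory) around a target mean function
  $g(i, m)$; the default shape has a bump at the second syllable
  ($g = 3.8$), a dip at the penultimate ($g = 2.4$ for $m \ge 4$), a longer
  final syllable ($g = 3.2$) and a baseline of 3 graphemes, over word
  lengths 1–6. The shifted-count noise law was chosen over Gaussian noise
  so that generated lengths are valid grapheme counts. Lengths are capped
  at 11 graphemes, the largest syllable the onset/coda constraints can
  realize; with the default means the cap correction is of order $10^{-5}$
  and far below sampling noise.

What the generators do **not** emulate: real orthography and morphology,
Zipfian token frequencies, inter-word dependence, digraphs, or
language-specific syllabification exceptions. Passing tests therefore
demonstrate that the *machinery* is correct — segmentation, binning,
fitting, and recovery of known structure under honest sampling noise — not
that any natural language obeys the fitted form.

## Statistical bands in the test suite

Stochastic checks compare simulation to exact theory in standard-error
units. Two multiplicity facts shape the assertions. A 3-SE band holds
per-cell with probability ≈ 99.7%, so across the ~21 supported cells of
the positional recovery check the joint "every cell inside 3 SE" event has
only ≈ 94% coverage per run; the suite accordingly asserts that at least
95% of cells sit inside 3 SE, all inside 4 SE, and that the generating
bump/dip shape is recovered exactly — the same "statistical band" style
used for the geometric cluster-length test, which requires the
goodness-of-fit not to reject at $\alpha = 0.01$ in at least 95% of seeded
runs. The million-symbol simulation check retains the strict every-bin
3-SE assertion because its ~25 bins are means of large samples with
near-Gaussian errors, and it passes with margin in practice.

## Problem sizes

The default test run simulates $10^5$–$10^6$ symbols per null-model check,
fits 200 noisy replicate profiles, round-trips $10^4$ generated words, and
analyzes synthetic corpora of 3,000–8,000 words; the whole suite completes
in well under a minute of compute. These sizes were chosen so that
sampling error is a small multiple of the tolerances being asserted;
nothing in the methodology changes at larger scale.

## Known limitations

* The one-vowel-nucleus approximation of the null model ignores diphthong
  and triphthong nuclei; the corpus summary's syllable-to-vowel ratio is
  the diagnostic for how much that matters for a given corpus.
* The sonority table is Latin-script only, and per-character: languages
  whose orthography encodes sonority in multigraphs will be segmented at
  the character level regardless.
* The syllabifier is one deterministic rule, not a model of any language's
  phonology; its value is reproducibility, not linguistic fidelity in
  every edge case.
* Corpus curation — language detection, deduplication, download — is
  upstream of this package; it consumes plain-text documents.
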