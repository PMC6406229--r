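---
title: "Dynamic word-recognition literacy tests and item-weighted kappa scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic word-recognition literacy tests and item-weighted kappa scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexlit)
```

## The measurement problem

Health literacy instruments built from a fixed item bank have three
structural weaknesses: the items leak and age, a single difficulty
profile produces ceiling effects in able populations, and nothing ties
the instrument to a domain of interest. `lexlit` treats the *generator*
as the instrument: any word-frequency corpus plus a seed yields a fresh,
reproducible Yes–No vocabulary test, and scores are comparable across
instantiations because both the item sampling design and the scoring
weights are functions of corpus frequency, not of the particular words
drawn.

The behavioral premise is that vocabulary knowledge tracks text
comprehension, and that word frequency orders difficulty: almost every
native speaker knows the most frequent words, so professing
unfamiliarity with them is strong evidence of limited literacy, while
rare words are unknown to most people and discriminate poorly.
Pseudoword foils calibrate for yea-saying: a respondent who claims to
know letter strings that are not words is partially guessing, and the
chance-correction in the score absorbs exactly that.

## Instrument design

From the (lexicon-filtered) vocabulary, sorted by count with a
lexicographic tie-break for determinism:

* **Tiers.** The vocabulary is split into 10 equally sized contiguous
  frequency tiers (earlier tiers take the extra word when the size is
  not divisible by 10).
* **True words.** 5 per tier, sampled uniformly without replacement.
* **Pseudowords.** 2 per tier, generated from random template words of
  the same tier; templates are never the sampled true words, so a
  pseudoword never appears alongside its visible source word.
* **Scale.** Each item is rated 1–4, from "never seen this word" to
  "sure I know its meaning".

The default design therefore presents 70 items. All sampling is driven
by one integer seed; the same corpus and seed reproduce the instrument
byte for byte.

## Item weights

Counts are log-transformed (natural log — any base cancels under the
z-score), standardized over the *full* filtered vocabulary, and passed
through a logistic:

$$u_n^{raw} = \frac{1}{1 + e^{-s\,(z_n - c)}}$$

with slope $s = 1$ and center $c = 0$ by default (both exposed).
Standardizing over the full vocabulary rather than the 50 sampled words
keeps a word's weight stable across instantiations drawn from the same
corpus, which is what makes scores comparable between forms. Each
pseudoword receives the arithmetic mean of the instrument's true-word
raw weights — pseudowords calibrate guessing and should neither dominate
nor vanish — and the 70 raw weights are then jointly normalized to sum
to 1. (Averaging before versus after normalization is equivalent here,
since normalization is a single global rescaling.)

## Scoring

The master key answers every true word 4 and every pseudoword 1. With
normalized item weights $u$, respondent categories $k$, key categories
$l$ and a disagreement weight $v(i,j)$ (linear $|i-j|$ by default,
quadratic optional):

* observed disagreement $q_o = \sum_n u_n\, v(k_n, l_n)$,
* chance disagreement $q_e = \sum_i \sum_j p^{(1)}(i)\, p^{(2)}(j)\,
  v(i,j)$, with $p^{(1)}(i) = \sum_n u_n [l_n = i]$ and $p^{(2)}(j) =
  \sum_n u_n [k_n = j]$ the item-weighted marginal category
  distributions,
* $\kappa = 1 - q_o / q_e$.

When all items carry weight $1/N$ this is exactly linearly weighted
Cohen's kappa computed from the $4 \times 4$ contingency table; the test
suite enforces that reduction against an independent contingency-table
implementation at $10^{-10}$ over 1000 randomized instances.

Numerical and degenerate-input choices:

* The literacy score is $\kappa$ clamped to $[0,1]$; the raw value is
  reported alongside it. Negative raw values are mathematically possible
  (systematically anti-key responding) and clamping preserves the
  score's intended 0–1 range without discarding information.
* Two identical constant raters give $q_o = q_e = 0$; the score is
  defined as 1 with a `degenerate` flag. $q_e = 0$ with $q_o > 0$ cannot
  occur for any symmetric zero-diagonal $v$ and is guarded as an
  internal error.
* Item weights must sum to 1 within $10^{-6}$ or scoring refuses;
  missing or duplicate answers are rejected, never imputed, because no
  principled missing-data rule exists for a knowledge self-report.
* Scores are invariant to item order and to positive rescaling of $v$
  (the constant cancels in $q_o/q_e$); both are property-tested.

## Pseudoword generation

The generator mirrors the standard subsyllabic-chain approach to
pseudoword stimuli. Every lexicon word is segmented deterministically:
maximal vowel runs become nuclei; `y` counts as a vowel only in words
with no other vowel letter (a word-level rule — a per-syllable rule
would be circular, since syllables do not exist before nuclei are
identified); all intervocalic consonants attach to the following onset
(a pure maximal-onset convention — without a phonotactic legality model,
"as many consonants as legally possible" degenerates to "all", and the
choice only shifts which strings count as attested transitions, not the
round-trip guarantee). Segmentations always concatenate back to the
source word.

Transition counts between consecutive nonempty elements (typed as
onset/nucleus/coda, so a coda `t` and an onset `t` are distinct) form a
first-order chain. Generation is a seeded random search: replace a
random nonempty subset of the template's elements with same-type
elements sampled proportional to lexicon frequency, and accept the first
candidate whose adjacent transitions are all attested, which differs
from the template, and which is not a lexicon word; the search gives up
after `max_attempts` (default 1000) and the instrument builder then
moves to another template. On a small closed lexicon the accepted set
provably lies inside the brute-force enumeration of chain-consistent
strings, which the tests exercise directly. Only structure- and
transition-matching are claimed — no graded phonotactic legality score.

## The synthetic test bench

Because the framework's empirical anchors (a books corpus, crowdsourced
respondents) are not shippable, the package carries a first-class
simulation module. It emulates:

* **Corpora** — Zipf-distributed counts `round(1e6 · rank^(-s))`
  (default exponent 1, so the top count exceeds the rank-1000 count
  about 1000-fold) over unique pronounceable consonant–vowel surfaces.
* **Respondents** — a graded-response model: for true words the latent
  familiarity is $a(\theta - b_n)$ plus standard-logistic noise, with
  ability $\theta \sim N(0,1)$, difficulty $b_n$ the negative
  standardized log frequency, and thresholds $\tau = (-1, 0, 1)$ cutting
  the latent scale into the four categories; for pseudowords, false
  alarms (categories 3–4) occur with probability
  $p_0\,(1 - \mathrm{logis}(s_p \theta))$, decreasing in ability. The
  defaults $a = 1.5$, $p_0 = 0.3$, $s_p = 1$ are fixtures chosen to give
  moderately noisy but informative 70-item tests; they are not claims
  about humans. The mass not allotted to false alarms splits so that a
  noise-free low-ability respondent with $p_0 = 0$ answers 1, matching
  the model's limiting logic.
* **Experiments** — parallel-form reliability (two surface-disjoint
  forms, shared respondents, Pearson r with a Fisher-z 95% CI, the CI
  style conventional for reliability coefficients) and criterion
  validity ($\theta$ plus Gaussian noise as the external criterion).
  Form disjointness is enforced because shared items would mechanically
  inflate the parallel-form correlation.

What the simulator does *not* emulate: real lexical statistics
(morphology, orthographic neighborhoods), respondent heterogeneity
beyond a single latent trait, inattention, or item-specific
idiosyncrasy. Passing simulation tests therefore demonstrates that the
pipeline is internally coherent — ability ordering is recovered, random
responding is chance-corrected to zero, parallel forms correlate — not
that any particular human correlation will be observed.

## Problem sizes and defaults

The shipped tests run on 1000-word synthetic vocabularies, 70-item
instruments, and 100–400 simulated respondents (1000 sheets for the
random-responder property; 1000 randomized instances for the oracle
equivalences) — sizes at which every experiment's sampling error is far
from its decision threshold. The quality-control filter defaults to
3 unambiguous check items; a sheet failing or missing any is dropped
before scoring. Quality-control item counts, design counts, logistic
parameters, disagreement scheme and all seeds are user-visible
arguments.

## Known limitations

* The subsyllabic chain is first-order; longer-range phonotactics (e.g.
  vowel harmony across syllables) are not modeled.
* The syllabifier is a heuristic for English-like orthography;
  languages with different vowel inventories need a different
  segmenter.
* Scores are reported without confidence intervals, and no grade-level
  cutpoints are defined for the clamped kappa.
* Item weights depend on the corpus: instruments built from different
  corpora are on different scales and should not be pooled.
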