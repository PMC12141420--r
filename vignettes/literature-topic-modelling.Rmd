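---
title: "Topic modelling of literature corpora: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topic modelling of literature corpora: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`littopics` implements a complete scientometric topic-modelling pipeline:
bibliographic ingestion and screening bookkeeping, abstract cleaning into a
document–term matrix (DTM), Latent Dirichlet Allocation (LDA) fitted by
collapsed Gibbs sampling, topic-number selection by block cross-validated
perplexity, and the derived statistics used to describe how a research
field's attention moves over time. This vignette explains the model, the
tunable parameters and their defaults, the numerical choices, what the
synthetic-data generator does and does not emulate, and the known
limitations.

## 1. Corpus ingestion and screening

Records carry `record_id`, `title`, `abstract`, `year`, `journal`,
`source_db` and an optional human screening flag. Three design points:

* **Duplicate definition.** Reference managers deduplicate with unstated
  rules, so we fix an explicit one: two records are duplicates when their
  *normalised titles* (casefolded, punctuation stripped, whitespace
  collapsed) **and** years both match; the first occurrence wins. Fuzzy
  (edit-distance) matching exists behind `fuzzy = TRUE` but is off by
  default — silently merging near-identical titles is a worse failure mode
  than occasionally keeping a duplicate.
* **Missing years** exclude a record from year-based analyses only; the
  record stays in the corpus because year matters only for trends.
* **Screening is human.** The package stores decisions, draws the seeded
  20% double-screening subset (`sampleScreeningSubset`), and computes
  Cohen's κ = (p₀ − pₑ)/(1 − pₑ) from the paired ratings. When both
  reviewers are constant and identical, pₑ = 1 and κ is undefined; the
  function signals a classed error rather than returning a number.

## 2. Abstract cleaning

The cleaning order is fixed and matters:

1. lowercase;
2. delete search-term phrases (`"phenolog*"` as a prefix pattern,
   multi-word phrases such as `"climate change"` as phrases) — these terms
   are in every abstract by construction of a literature search and carry
   no discriminating signal;
3. hyphens and forward slashes become spaces;
4. all remaining punctuation is deleted in place (so word-internal
   apostrophes close up instead of splitting a token);
5. whitespace tokenisation;
6. removal of number-words (cardinals and ordinals, zero–trillion),
   English stop-words, and publisher boilerplate terms (copyright lines);
   all three lists ship as editable text files and are placeholders to be
   extended per corpus;
7. Porter suffix-stripping stemming, implemented in full from the classic
   rule tables (no stemming package is declared as a dependency); tokens of
   one or two characters or containing non-letters pass through unchanged;
8. a stem-level safety net deletes search-term stems again (prefix
   `phenolog` and the stemmed bigrams `climat chang`, `global chang`,
   `global warm`), because hyphenated variants like *climate-change* only
   become visible after step 3.

Stems occurring in five or fewer documents are then removed
(`minDocFrequency = 6`), in a single pass — iterating the filter to a fixed
point would entangle the vocabulary with document deletions. Documents
emptied by the filter remain as flagged all-zero rows, excluded from
fitting but preserved for bookkeeping. The vocabulary is sorted in the C
locale so every downstream table is reproducible across platforms.
Stemming is not idempotent for a handful of stems (`agre` → `agr`); this
is a property of the classic algorithm, applied once, and is logged by the
test suite rather than "fixed".

## 3. The LDA sampler

Collapsed Gibbs sampling resamples each token's topic from
p(z = k | rest) ∝ (n_dk + α)(n_kv + β)/(n_k· + Vβ). Defaults follow the
conventions of widely used Gibbs implementations: α = 50/K, β = 0.1,
2000 sweeps with 1000 burn-in, a single chain. φ and θ are posterior
means from the final count state; `average = TRUE` instead averages
posterior-mean estimates every `sampleEvery` post-burn-in sweeps. Averaging
gives smoother estimates but blurs token-level assignments across
label-switching, so the final-state estimate is the default.

**Determinism by construction.** All randomness comes from counter-based
per-document streams keyed by (seed, canonical document index), and sweeps
visit documents in canonical order — the lexicographic order of their
record ids — regardless of input row order. Consequently (a) a fixed seed
reproduces φ, θ and z bit-identically on any platform, and (b) permuting
the input rows permutes θ rows exactly, a property the test suite asserts.
Convergence is *not* detected automatically; the per-sweep collapsed joint
log-likelihood is exposed (`logLikTrace`) for inspection.

## 4. Perplexity and choosing K

Held-out documents are scored by document completion: a seeded permutation
of the document's tokens is split in half, the first half is folded in by
50 short Gibbs sweeps against fixed φ to estimate θ_d, and the second half
is scored under Σ_k θ_dk φ_kv. Perplexity is exp(−mean log predictive
likelihood); a uniform predictor over V words scores exactly V, which the
tests verify to 1e−10. Held-out tokens outside the model vocabulary are
excluded with a warning and a count.

Cross-validation partitions documents into contiguous blocks of a seeded
shuffle (5 folds by default; document-level disjoint folds are the natural
reading of "block" cross-validation for exchangeable documents). The
default grid is K ∈ {10, 20, 30, 40, 50, 60, 100, 200}. Because perplexity
typically keeps improving past the point where topics remain
interpretable, the result reports **both** the argmin and a tolerance-based
elbow — the smallest K beyond which the relative improvement in mean
perplexity falls below `tol` (default 0.05) — and the package never
silently picks one: an analysis configuration must name its rule. Cells
where K reaches the training-document or training-vocabulary count are
invalid and excluded. Fold fits default to 500 sweeps / 250 burn-in:
screening eight K values at five folds is a 40-fit workload, and model
ranking stabilises long before the final-fit sweep count is needed.

## 5. Derived statistics

* **Decadal prevalence** sums θ per topic over the articles of each decade
  (decade = ⌊year/10⌋·10; default window 1990s–2010s, so a lone 1989
  article or anything past 2019 is excluded and counted in a log). Since θ
  rows sum to one, each decade column sums to its article count — a
  conservation law the tests assert. A rank-by-decade table accompanies
  the weights.
* **Co-occurrence** log10-transforms θ (smoothed posterior means are
  strictly positive; raw zeros are rejected with advice) and computes
  Euclidean distances between the per-topic weight profiles across
  documents. Mapping distances to the 0–1 "never to always co-occur"
  scale requires inverting and rescaling; the default is 1 − d/d_max with
  d_max the largest off-diagonal distance, a min–max variant is available,
  and the raw distance matrix is always returned alongside, because the
  rescaling convention is a genuine free choice.
* **Generality vs. specificity** selects each article's highest-weighted
  topic, breaking ties by lowest topic index (logged); a topic never
  selected reports `n_selected = 0` and a *missing* selected mean, never a
  fabricated 0.
* **Article–topic frequency** is emitted in both defensible readings —
  argmax counts per topic and the per-topic histogram of weights — since
  "frequency of topics given the topic weight" is ambiguous between them.
* **Journal contribution** ranks journals by article count (ties
  lexicographic) and reports cumulative top-N shares plus per-journal
  topic profiles (mean θ and argmax counts).

## 6. Topic popularity GLMM

Counts y_kt (articles per topic per year, argmax assignment, zero-filled
grid) follow a Poisson GLMM with log link:

log E[y_kt] = μ + γ·t + b0_k + b1_k·t,  (b0_k, b1_k) ~ N(0, Σ),

with t the centred, unit-variance scaled year. Scaling is a conditioning
choice: it leaves the *signs* of the random effects — the basis of the
hot/cold classification — unchanged. Estimation is Laplace-approximated
maximum likelihood (`lme4::glmer`, nAGQ = 1), which is deterministic;
random effects are empirical-Bayes conditional modes, which the tests show
are shrunk relative to independent per-topic Poisson GLMs and converge to
them as information grows. Non-convergence is flagged, never silent. A
weighted-count variant (summing θ instead of argmax) exists for
sensitivity analysis but is not the Poisson response. The companion
simulator `simulateTopicYearCounts` draws from this model with the slope
variance expressed **per calendar year** (a topic trend of ±10%/year),
the scale at which such trends are scientifically interpretable.

## 7. Country extraction

Raw (pre-cleaning) abstracts are searched for every country name and
alias, token-boundary anchored and case-insensitive — so *Nigeria* never
counts for *Niger* — with set semantics per article. Aliases that are also
ordinary English words or personal names (Georgia, Jordan, Chad, Turkey,
US, ...) are matched only when capitalised in the source, switchable via
`matchAmbiguousLowercase`. The shipped alias file (ISO-style country list
plus common variants: UK/Britain, USA/America, Burma/Myanmar, ...) is
editable data, and alias maps round-trip through YAML with identical
matching behaviour. No fuzzy matching and no affiliation geolocation: the
method counts literal mentions, nothing more.

## 8. The synthetic-data generator

`generateCorpus` emulates the corpus a literature synthesis would analyse:
D = 500 abstracts of mean length 100 (Poisson) over V = 500 pseudo-word
stems, K = 5 topics with sparse topic-word distributions (β_true = 0.01)
and concentrated document mixtures (α_true = 0.1), years 1989–2019 with
publication volume growing ~8%/year, 25 journals with Zipf-distributed
shares, and a fifth of abstracts naming a study country. Topic prevalence
shifts over time by tilting the Dirichlet prior through a softmax in the
standardised year — topics themselves stay fixed, matching the analysis
assumption that prevalence, not meaning, changes. Pseudo-words (`w0001`,
...) pass through cleaning untouched, so recovery tests are independent of
stemmer behaviour; `injectNoise` adds the decoys (stop-words, number
words, hyphenated search-term variants, publisher boilerplate, optional
rare terms) that exercise the cleaning contract, with every injection
logged for exact assertions.

What it does **not** emulate: natural English morphology (stemming is
exercised only via decoys and unit tests), citation structure, abstract
discourse structure, correlated topics within themes, and
database-specific metadata quirks. Passing recovery tests therefore shows
the *algorithmic* pipeline is correct under its own generative
assumptions, not that a particular real corpus satisfies them.

## 9. Validation problem sizes

The shipped validation suite runs at sizes chosen to give decisive
answers on a single CPU: exact enumeration on a 2-document, 3-word, K = 2
instance (all 32 assignments); recovery and model selection on the
K_true = 5 / V = 500 / D = 500 corpus (2000-sweep fits; 3-fold CV at 400
sweeps for the K = 2 vs K = 5 contrast); GLMM recovery with 40 topics and
30 years; brute-force agreement of every derived statistic on ≤10-document
toys; and a full-pipeline byte-identity check at D = 150. Under these
conditions matched topic cosines exceed 0.99, cross-validated perplexity
at the true K beats an underfitted K = 2 by ~40%, and GLMM slope recovery
correlates with truth above 0.99.

## 10. Known limitations

* Single-chain sampling with no automatic convergence diagnostics beyond
  the log-likelihood trace; label switching across runs is expected and is
  why recovery tests match topics before comparing.
* The stop-word and publisher-term lists are deliberately minimal
  defaults; real corpora need corpus-specific extensions.
* The fold-in half/half split scores short documents with little
  information (a one-token document contributes nothing to evaluation).
* Country matching is literal; study sites described without naming a
  country, or named at sub-national level, are invisible.
* The elbow rule depends on its tolerance; reporting both elbow and argmin
  is a mitigation, not a resolution, of the inherent subjectivity in
  choosing K.
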