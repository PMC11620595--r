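---
title: "Matching free-text addresses to a care home registry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching free-text addresses to a care home registry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carehomematch)
```

## The problem

Care home residents are a vulnerable, high-need population, yet routine
health data rarely records residency explicitly. What the data does carry is
a free-text address typed in at GP registration: no fixed layout, optional
or misplaced postcodes, abbreviations, typos, and the same true address
written many different ways over the years ("10 Glebe Street", "Ten Glebe
Street", "10 Glebe St"). The regulator, by contrast, publishes a clean
registry of care home services with names, addresses and postcodes.
`carehomematch` decides, for each unique written address, whether it is a
care home address, by combining rule-based filtering with fuzzy similarity
scoring against the registry.

## The pipeline

The decision for each address proceeds through three sequential stages:

1. **Filtering.** Rule 1: if the *first* address line contains a care home
   name phrase ("care home", "nursing home", "residential home"; the
   lexicon is configurable) the address is accepted as a care home
   immediately. Rule 2: the address is rejected if its normalized postcode
   matches no registry postcode, or every registry entry at that postcode is
   registered for a different kind of care service, or no registry town
   appears anywhere in its text. Rule order matters and is pinned by a
   regression test: an address whose first line says "care home" is accepted
   even if its postcode matches nothing.
2. **Preprocessing.** Lines are split at commas, lowercased, hyphens become
   spaces, punctuation is dropped, and tokens containing digits are pulled
   out into a separate number list ("Flat 3B, 12/4 High St" becomes lines
   `flat`, `high st` with numbers `3b`, `124`). The surviving text is joined
   into one comparison string per address and, for the vector-space methods,
   turned into a character n-gram count vector.
3. **Scoring and thresholding.** Each surviving address is compared against
   the care-home-typed registry entries that share its exact postcode
   (postcode *blocking*: rule 2 already discarded everything else). The best
   score per method is kept and compared with a decision threshold fitted on
   the training split.

## Similarity methods

Eleven methods are implemented, in two families.

**Edit-distance family** (string similarity in [0, 1], higher is better):
Levenshtein ratio `1 - d/max(|a|,|b|)`; Damerau-Levenshtein ratio (optimal
string alignment: adjacent transposition counts one edit); Jaro-Winkler
(prefix scale 0.1, max prefix 4); LCS ratio `2*LCS/(|a|+|b|)`. Two empty
strings are perfectly similar. The kernels are C++ (Rcpp) and every one is
checked against an independent pure-R dynamic-programming reference on a
thousand random pairs.

**Vector-space family** (distance ≥ 0 over character n-gram vectors, lower
is better): city block, Euclidean, Chebyshev, Bray-Curtis, cosine,
correlation (`1 - Pearson r`), and Jensen-Shannon. Jensen-Shannon uses the
square-root, base-2 form `sqrt(KL(u||m)/2 + KL(v||m)/2)` with
`m = (u+v)/2`, which is a metric and bounded in [0, 1]; it therefore
operates on probability-normalized vectors, while the other six operate on
raw counts. Zero or constant vectors have no cosine/correlation distance;
the scorer treats such candidates as ineligible rather than inventing a
value.

The default n-gram length is 2: character bigrams tolerate single typos
while still distinguishing street names at practical vocabulary sizes
(`ngram_n` is configurable). The vocabulary is built once from the registry
plus the training-split survivors and reused unchanged for validation
(out-of-vocabulary n-grams are ignored), the usual fit/transform discipline.

## The number-token gate

Postcode blocking leaves one hard confusable: the neighbour at the same
postcode. "14 High St, Kirkcaldy" differs from the care home at "12 High
St" by a single character, so string similarity alone is nearly useless at
this range. The extracted number tokens resolve it: when both the address
and a candidate carry number tokens, they must share at least one,
otherwise the candidate is ineligible; if either side has no numbers the
gate stands open. The fragments of the address's own postcode are excluded
from its gate tokens — the postcode is already compared exactly by
blocking, and leaving its pieces in would let every blocked pair through.
For the same reason the registry comparison string is the cleaned name,
address and town *without* the postcode. The gate is on by default and can
be disabled (`number_gate = FALSE`).

## Baselines

Three comparators reproduce the methods this approach is measured against.
**Postcode matching** allocates every address whose postcode appears in the
care home list — simple, sensitive, and imprecise exactly because
neighbours share postcodes. The **Markov score** is a first-order character
transition chain trained on the cleaned registry texts; a string scores 100
times the geometric mean of its add-k-smoothed transition probabilities
(k = 1 by default), so scores live on a 0-100 scale. Smoothing divides by
`n_from + k*(A+1)` where A is the alphabet size; the extra slot absorbs
characters never seen in training. The **Phonics score** tokenizes both
strings, encodes each token phonetically and reports the multiset overlap
of codes over the larger token count. The encoder is American Soundex,
implemented here and verified against hand-worked reference codes; the
`encoder` argument accepts any token-to-code function. Baselines do not use
the sequential filters; the phonics baseline shares the postcode blocking
of the main methods to keep its candidate search bounded.

## Threshold fitting

For each method and stratum the decision threshold is chosen on the
training split to maximize F1. Candidate cut-points are midpoints between
consecutive distinct scores plus sentinels beyond both extremes, so a
fitted threshold never sits exactly on a training score; ties break toward
higher PPV, then toward the more conservative threshold (higher for
similarity, lower for distance). Classification is inclusive (`>=` / `<=`),
resolving boundary ties toward a positive call, which suits a screening
use. Fitting is equivalent to exhaustive search over all cut-points — an
oracle test asserts this on a hundred random instances. Addresses whose
candidates were all gated out are never classified positive, whatever the
threshold; they are likewise excluded from fitting. Thresholds are fitted
independently per (region × age stratum), since score distributions differ
between the whole population and the over-65 subset.

## Evaluation

Performance is reported as PPV `tp/(tp+fp)`, sensitivity `tp/(tp+fn)` and
F1, their harmonic mean, as percentages. Two levels: **address level**
counts each unique written address once; **patient level** weights each
address by its resident count on the snapshot date, so historical forms
(zero residents) contribute nothing and a misclassified large home costs
proportionally. Undefined metrics (no predicted positives, or no gold
positives) are flagged `NA`, never silently zeroed. The over-65 stratum
restricts to addresses where at least one resident is aged 65+, as carried
by the input schema; the package does not infer ages.

## The synthetic corpus generator

The real register is confidential, so the generator builds corpora with the
same *structure*: by default 1.3% of unique written addresses are care home
forms while roughly 0.7% of people are care home residents. Each service
emits 1-5 unique written forms — formatting variants (merged lines,
one-line forms, unspaced postcodes) plus noise — and exactly one form
carries the service's current residents; the remainder are historical.
Because the positive-form budget and the resident budget are both anchored
to those fractions, the implied mean residents per service is small
(`resident_fraction * n_addresses / n_services`, about 1.6 at the
defaults): the corpus emulates a register dominated by many small services
and by historical forms, which is precisely what makes the address level
harder than the patient level. `mean_care_home_size` can be set explicitly
to model larger homes.

Noise is applied per independent draw: character typos
(substitute/delete/transpose, rate per alphanumeric character), street-word
abbreviation ("street" → "st"), spelled-out house numbers ("10" → "ten"),
comma-merging and shuffling of lines, and dropping the care home name line.
A `neighbour_rate` fraction of ordinary households is placed at a care
home's postcode with a disjoint house number — the adversarial case the
number gate exists for. All draws flow through R's RNG under a single
configured seed; regeneration is byte-identical.

What the generator does *not* emulate: real UK address geography and
postcode density, non-English spellings, OCR-style corruption, sheltered
housing and other congregate settings that are not care homes, and
gold-standard labelling error. Passing the synthetic checks therefore shows
the machinery is correct and robust to the modelled noise; it does not
certify performance on any particular health board's data, which varies
regionally and should be validated locally.

## Numerical and design choices

- **Postcode normalization**: uppercase, collapse whitespace, locate the
  last UK-shaped token (outward code, then digit-letter-letter inward) and
  re-insert the canonical single space. Idempotent; absence is `NA`, not an
  error.
- **Degenerate inputs**: empty cleaned text cannot be Markov-scored
  (explicit error); all-zero n-gram vectors are flagged and excluded from
  cosine/correlation/Jensen-Shannon scoring via candidate ineligibility.
- **Single-class training strata**: `fit_threshold()` refuses label sets
  with one class; the pipeline falls back to the tightest threshold
  covering the observed class, which matters only for tiny strata.
- **Determinism**: the split, the generator and every scorer are
  deterministic given seeds; two runs with the same configuration produce
  byte-identical output files. Vocabulary order is fixed by C-locale radix
  sort.
- **Problem sizes in the checks**: the oracle comparisons use 1,000 random
  pairs per family and 100 random threshold instances of size ≤ 200; the
  end-to-end checks use a noise-free corpus of 5,000 addresses (where every
  method must be perfect at both levels) and a noisy corpus of 20,000
  addresses with 2% typo, 30% abbreviation and 20% name-drop rates (where
  the best vector-space method must reach patient-level F1 ≥ 90% on
  validation and every vector-space method must beat the Markov baseline).
  The trend check (more typos never help) uses 2,500-address corpora over
  five seeds.

## Worked example

```{r example}
cfg <- synthetic_config(n_addresses = 2000, typo_rate = 0.02,
                        abbreviation_rate = 0.3, name_drop_rate = 0.2,
                        seed = 42)
corpus <- generate_corpus(cfg)
res <- run_pipeline(run_config(methods = c("city_block", "cosine"),
                               baselines = "markov_score", seed = 1),
                    addresses = corpus$addresses,
                    registry = corpus$registry)
subset(as.data.frame(res$report), stratum == "all_ages",
       select = c(method, level, ppv, sensitivity, f1))
res$log$validation
```

## Known limitations

Exact-postcode blocking means an address whose postcode was mistyped can
only be recovered by filter rule 1 (its name phrase); this is a real
failure mode of the design, visible in the sensitivity ceiling under heavy
typo noise. The Markov and Phonics formulations follow the published score
semantics (0-100 scale, phonetic overlap) but their original construction
details are not public, so they are this package's own faithful
reconstructions, not numerical replicas. Threshold fitting optimizes
address-level F1 by default; fitting on patient-level weights is a
straightforward extension not currently exposed.
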