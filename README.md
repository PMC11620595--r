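# carehomematch

Identify care home residents from free-text GP-registered addresses.

Routine health data rarely says who lives in a care home, yet that is
exactly the population hit hardest when services are stretched. What the
data does hold is a free-text address per patient — typed at GP
registration with no format guarantees — and, on the other side, a clean
regulator registry of care home services. `carehomematch` decides, for each
unique written address, whether it is a care home address, and evaluates
the decision both per address and per resident.

## Method

The pipeline has three sequential stages:

1. **Rule filtering.** An address is accepted outright if its first line
   contains a care home name phrase ("care home", "nursing home",
   "residential home"); it is rejected if its postcode matches no registry
   postcode, or only matches services of a different kind, or it names no
   registry town. Survivors go on to scoring.
2. **Preprocessing.** Comma splitting, lowercasing, hyphen and punctuation
   handling, and extraction of digit-bearing tokens into a separate number
   list: `"89 Bay Street, Newtown-on-Bay"` → lines `[bay street, newtown on
   bay]`, numbers `[89]`. Text is optionally vectorized as character
   n-gram counts (default bigrams).
3. **Similarity scoring and thresholding.** Each survivor is compared to
   the care homes sharing its exact postcode under eleven methods — four
   edit-distance similarities (Levenshtein, Damerau-Levenshtein,
   Jaro-Winkler, LCS ratio) and seven vector-space distances (city block,
   Euclidean, Chebyshev, Bray-Curtis, cosine, correlation,
   Jensen-Shannon) — with a number-token gate that keeps the neighbour at
   "14 High St" from matching the care home at "12 High St". A per-method,
   per-stratum threshold maximizing F1 = 2·PPV·sensitivity/(PPV +
   sensitivity) is fitted on a 70% training split and applied to the 30%
   validation split.

Three baseline comparators are included (postcode matching, a Markov
character-chain score on a 0-100 scale, a phonetic token-overlap score),
plus a synthetic corpus generator that emulates the structure of a real
register — ~1.3% care home addresses, several written forms per care home,
typos, abbreviations, neighbours at shared postcodes — so the whole system
is testable without any confidential data.

## Worked example

```r
library(carehomematch)

cfg <- synthetic_config(n_addresses = 10000, typo_rate = 0.02,
                        abbreviation_rate = 0.3, name_drop_rate = 0.2,
                        seed = 42)
corpus <- generate_corpus(cfg)
res <- run_pipeline(run_config(methods = c("city_block", "cosine"),
                               baselines = "markov_score", seed = 1),
                    addresses = corpus$addresses,
                    registry = corpus$registry)
subset(as.data.frame(res$report), stratum == "all_ages",
       select = c(method, level, ppv, sensitivity, f1))
#>         method   level    ppv sensitivity    f1
#> 1   city_block address 100.00        87.2 93.15
#> 2   city_block patient 100.00        74.1 85.11
#> 3       cosine address 100.00        92.3 96.00
#> 4       cosine patient 100.00        81.5 89.80
#> 5 markov_score address  15.62        12.8 14.08
#> 6 markov_score patient   6.98        11.1  8.57
res$log$validation
#>               total     rule1_care_home rule2_not_care_home              scored
#>                3000                  22                2913                  65
```

Reading: on a noisy 10,000-address synthetic register, cosine similarity
identifies 92.3% of care home address forms (address-level sensitivity)
with no false positives (PPV 100%), while the Markov baseline collapses;
the patient level weights each address by its residents. The log shows the
filter stages: of 3,000 validation addresses, 22 were accepted by the
name-phrase rule, 2,913 rejected by the exclusion rule, and 65 went to
similarity scoring.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/carehome-match.R generate --n 10000 --seed 1 --typo 0.02 --out corpus/
Rscript inst/cli/carehome-match.R all --addresses corpus/addresses.csv \
    --registry corpus/registry.csv --seed 1 --out run/
```

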