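Package: carehomematch
Title: Identify Care Home Residents from Free-Text Address Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether a free-text GP-registered address is a
    care home address by matching it against a regulator's registry of care
    home services. Implements the full pipeline: sequential rule-based
    filtering (name-phrase, postcode/service-type/town exclusion), address
    text cleaning with number-token extraction, character n-gram vector
    representations, eleven string and vector-space similarity measures with
    postcode blocking, baseline comparators (postcode matching, a Markov
    character-chain score, a phonetic token-overlap score), training-set
    threshold optimisation, and evaluation by positive predictive value,
    sensitivity and F1 at address and patient level. Includes a synthetic
    address-corpus generator with known ground truth so the whole pipeline
    can be exercised without access to confidential health records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
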