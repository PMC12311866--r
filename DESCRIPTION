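Package: hlaprofiler
Title: Population-Level HLA-Disease Association Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds per-allele profiles of the ecological association
    between HLA allele population frequencies and log-transformed disease
    prevalence across countries: Pearson correlations Fisher z-transformed
    to r', behind a country-coverage filter. Includes the published
    127-allele type 1 diabetes reference profile for 14 Continental
    Western European countries, the profile-level inference battery
    (sign-split proportion tests, ANOVA of r' by sample size, nested
    class/gene ANOVA, strength t-tests), readers for
    allelefrequencies.net-style exports, a synthetic-data generator with
    parameter-recovery experiments, and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
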