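# In-code fixtures: small tables built programmatically, no files shipped.

# Frequency table for `n_alleles` alleles over `countries`, values supplied
# or drawn from the current RNG stream.
make_freq_df <- function(alleles, countries, frequency = NULL) {
  df <- expand.grid(allele = alleles, country = countries,
                    stringsAsFactors = FALSE)
  df$frequency <- if (is.null(frequency)) {
    round(stats::runif(nrow(df), 0.01, 0.3), 4)
  } else {
    frequency
  }
  df
}

make_prev_df <- function(countries, prevalence_pct = NULL) {
  if (is.null(prevalence_pct)) {
    prevalence_pct <- round(stats::runif(length(countries), 0.1, 0.9), 4)
  }
  data.frame(country = countries, prevalence_pct = prevalence_pct,
             stringsAsFactors = FALSE)
}

# Build an hla_profile through the public TSV reader (profile column layout).
make_profile <- function(allele, n, r_prime, r = tanh(r_prime)) {
  tsv <- tempfile(fileext = ".tsv")
  if (length(allele) == 0L) {
    df <- data.frame(index = integer(), allele = character(),
                     class = character(), gene = character(),
                     n = integer(), r = numeric(), r_prime = numeric())
  } else {
    parsed <- parse_hla_allele(allele)
    df <- data.frame(index = seq_along(allele), allele = parsed$allele,
                     class = parsed$hla_class, gene = parsed$locus,
                     n = n, r = r, r_prime = r_prime)
  }
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  on.exit(unlink(tsv))
  read_profile(tsv)
}

# Independent one-pass Pearson oracle from the raw sum formula.
pearson_sum_formula <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Exact two-sided binomial p by full enumeration: sum probabilities of all
# outcomes no more likely than the observed one.
binom_enumeration <- function(k, n, p0) {
  probs <- stats::dbinom(0:n, n, p0)
  sum(probs[probs <= probs[k + 1L] * (1 + 1e-07)])
}
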