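# Readers/writers for the two input table formats, the packaged reference
# profile, and the JSON statistics report.

#' Construct an allele-frequency table
#'
#' Validates and normalizes a data.frame of allele-by-country population
#' frequency observations. The table is sparse: an allele need not be
#' reported in every country.
#'
#' @param df A data.frame with columns `allele`, `country`, `frequency`.
#' @return An object of class `allele_freq_table` (a data.frame with columns
#'   `allele`, `locus`, `hla_class`, `country`, `frequency`).
#' @export
allele_frequency_table <- function(df) {
  need <- c("allele", "country", "frequency")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  parsed <- parse_hla_allele(df$allele)
  freq <- as.numeric(df$frequency)
  if (any(is.na(freq))) stop("non-numeric frequency value", call. = FALSE)
  if (any(freq < 0 | freq > 1)) {
    stop("allele frequency outside [0, 1]: ",
         signif(freq[freq < 0 | freq > 1][1L], 4), call. = FALSE)
  }
  out <- data.frame(
    allele = parsed$allele,
    locus = parsed$locus,
    hla_class = parsed$hla_class,
    country = normalize_country(df$country),
    frequency = freq,
    stringsAsFactors = FALSE
  )
  key <- paste(out$allele, out$country, sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate (allele, country) pair: ",
         key[duplicated(key)][1L], call. = FALSE)
  }
  structure(out, class = c("allele_freq_table", "data.frame"))
}

#' Read allele population frequencies
#'
#' Two dialects are supported: `simple_csv` with columns
#' `allele,country,frequency`, and `afnd_export` mirroring the
#' allelefrequencies.net query export with columns `Allele`,
#' `Population/Country` (or `Country`/`Population`) and
#' `Overall Allele Frequency`. Frequencies are proportions in \[0, 1\]
#' unless `percent = TRUE` or the frequency column header itself says
#' percent.
#'
#' @param file Path or connection to a delimited text file with a header row.
#' @param dialect `"simple_csv"` or `"afnd_export"`.
#' @param percent If `TRUE`, input frequencies are percentages and are
#'   divided by 100.
#' @return An [allele_frequency_table()] object.
#' @export
read_allele_frequencies <- function(file,
                                    dialect = c("simple_csv", "afnd_export"),
                                    percent = FALSE) {
  dialect <- match.arg(dialect)
  raw <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "simple_csv") {
    need <- c("allele", "country", "frequency")
    miss <- setdiff(need, names(raw))
    if (length(miss) > 0L) {
      stop("missing column(s) in simple_csv input: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    df <- raw[, need]
  } else {
    acol <- intersect(c("Allele", "allele"), names(raw))[1L]
    ccol <- intersect(c("Population/Country", "Country", "Population"),
                      names(raw))[1L]
    fcol <- grep("Overall Allele Frequency", names(raw),
                 fixed = TRUE, value = TRUE)[1L]
    if (is.na(acol) || is.na(ccol) || is.na(fcol)) {
      stop("afnd_export input must have Allele, Population/Country and ",
           "Overall Allele Frequency columns", call. = FALSE)
    }
    if (grepl("%|percent", fcol, ignore.case = TRUE)) percent <- TRUE
    df <- data.frame(allele = raw[[acol]], country = raw[[ccol]],
                     frequency = raw[[fcol]], stringsAsFactors = FALSE)
  }
  df$frequency <- as.numeric(df$frequency)
  if (percent) df$frequency <- df$frequency / 100
  allele_frequency_table(df)
}

#' Construct a country prevalence table
#'
#' @param df A data.frame with column `country` plus either `cases` and
#'   `population` (counts of persons) or `prevalence_pct` directly.
#' @return An object of class `prevalence_table` (a data.frame with columns
#'   `country`, `cases`, `population`, `prevalence_pct`, `log_prevalence`).
#'   `log_prevalence` is the natural log of the percent prevalence.
#' @export
prevalence_table <- function(df) {
  if (!"country" %in% names(df)) {
    stop("missing 'country' column", call. = FALSE)
  }
  country <- normalize_country(df$country)
  if (anyDuplicated(country)) {
    stop("duplicate country: ", country[duplicated(country)][1L],
         call. = FALSE)
  }
  if (all(c("cases", "population") %in% names(df))) {
    cases <- as.numeric(df$cases)
    population <- as.numeric(df$population)
    pct <- prevalence_pct(cases, population)
  } else if ("prevalence_pct" %in% names(df)) {
    cases <- rep(NA_real_, nrow(df))
    population <- rep(NA_real_, nrow(df))
    pct <- as.numeric(df$prevalence_pct)
  } else {
    stop("need either cases+population or prevalence_pct columns",
         call. = FALSE)
  }
  if (any(is.na(pct)) || any(pct <= 0)) {
    stop("prevalence must be positive for log transformation", call. = FALSE)
  }
  if (any(pct > 100)) stop("prevalence exceeds 100%", call. = FALSE)
  out <- data.frame(
    country = country, cases = cases, population = population,
    prevalence_pct = pct, log_prevalence = log(pct),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("prevalence_table", "data.frame"))
}

#' Read a country prevalence table
#'
#' @param file Path or connection to a CSV with columns
#'   `country,cases,population` or `country,prevalence_pct`.
#' @return A [prevalence_table()] object.
#' @export
read_prevalence <- function(file) {
  prevalence_table(utils::read.csv(file, stringsAsFactors = FALSE))
}

#' The packaged population-level HLA-T1D reference profile
#'
#' Loads the published 127-allele type 1 diabetes profile for 14 Continental
#' Western European countries that ships with the package: per allele, the
#' number of countries N used and the Fisher z-transformed correlation r'
#' between allele population frequency and log percent T1D prevalence
#' (printed to 3 decimals). Integrity is checked on every load: 127 entries,
#' N between 9 and 14, and the stored class column equal to the class
#' derived from each allele's locus.
#'
#' @return An object of class `hla_profile` (see [hla_profile()]); the `r`
#'   column is back-computed as `tanh(r_prime)`.
#' @export
#' @examples
#' prof <- t1d_profile()
#' nrow(prof)  # 127
t1d_profile <- function() {
  path <- system.file("extdata", "t1d_profile.tsv", package = "hlaprofiler",
                      mustWork = TRUE)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  parsed <- parse_hla_allele(raw$allele)
  if (nrow(raw) != 127L) {
    stop("reference profile corrupted: expected 127 entries, got ",
         nrow(raw), call. = FALSE)
  }
  if (!all(raw$class == parsed$hla_class)) {
    stop("reference profile corrupted: stored class disagrees with locus",
         call. = FALSE)
  }
  if (any(raw$n_countries < 9L | raw$n_countries > 14L)) {
    stop("reference profile corrupted: N outside [9, 14]", call. = FALSE)
  }
  df <- data.frame(
    allele = parsed$allele,
    locus = parsed$locus,
    hla_class = parsed$hla_class,
    n_countries = as.integer(raw$n_countries),
    r = tanh(raw$r_prime),
    r_prime = raw$r_prime,
    stringsAsFactors = FALSE
  )
  new_hla_profile(df, min_countries = 9L,
                  source = "packaged T1D reference profile (14 CWE countries)")
}

#' Write / read a profile as TSV
#'
#' Deterministic column order (`index`, `allele`, `class`, `gene`, `n`, `r`,
#' `r_prime`), "." decimal separator, UTF-8; round-trips through
#' [read_profile()].
#'
#' @param profile An `hla_profile` object.
#' @param file Output path.
#' @return `write_profile()` returns `file` invisibly; `read_profile()`
#'   returns an `hla_profile`.
#' @export
write_profile <- function(profile, file) {
  stopifnot(inherits(profile, "hla_profile"))
  df <- as.data.frame(profile)
  out <- data.frame(
    index = seq_len(nrow(df)),
    allele = df$allele,
    class = df$hla_class,
    gene = df$locus,
    n = df$n_countries,
    r = df$r,
    r_prime = df$r_prime,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(file)
}

#' @rdname write_profile
#' @export
read_profile <- function(file) {
  raw <- utils::read.delim(file, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  if (nrow(raw) == 0L) {
    df <- data.frame(allele = character(), locus = character(),
                     hla_class = character(), n_countries = integer(),
                     r = numeric(), r_prime = numeric(),
                     stringsAsFactors = FALSE)
    return(new_hla_profile(df, min_countries = NA_integer_, source = file,
                           reorder = FALSE))
  }
  need <- c("allele", "n", "r", "r_prime")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L) {
    stop("missing profile column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  parsed <- parse_hla_allele(raw$allele)
  df <- data.frame(
    allele = parsed$allele,
    locus = parsed$locus,
    hla_class = parsed$hla_class,
    n_countries = as.integer(raw$n),
    r = as.numeric(raw$r),
    r_prime = as.numeric(raw$r_prime),
    stringsAsFactors = FALSE
  )
  new_hla_profile(df, min_countries = NA_integer_, source = file,
                  reorder = FALSE)
}

#' Serialize a statistics report to JSON
#'
#' Each test entry carries `test`, `statistic`, `df`, `p_value` and `groups`;
#' the file round-trips through [read_stats_report()].
#'
#' @param report An `hla_stats_report` (from [profile_stats()]) or a list of
#'   test entries.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_stats_report <- function(report, file) {
  jsonlite::write_json(unclass(report), file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(file)
}

#' @rdname write_stats_report
#' @export
read_stats_report <- function(file) {
  structure(jsonlite::read_json(file, simplifyVector = TRUE),
            class = "hla_stats_report")
}
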