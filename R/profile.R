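# Core computation: coverage filtering, per-allele correlation of allele
# population frequency with log prevalence, Fisher z-transform, ranking.

#' Fisher z-transform of a correlation coefficient
#'
#' `fisher_z(r) = atanh(r) = 0.5 * log((1 + r) / (1 - r))`, the variance
#' stabilizing transform applied to every per-allele correlation in a
#' profile. `|r| >= 1` is a domain error (it would map to +/-Inf and poison
#' downstream ANOVA); callers working with degenerate, perfectly collinear
#' inputs may set `clamp = TRUE` to pull such r to `+/-(1 - 1e-12)` first.
#'
#' @param r Numeric vector of correlations.
#' @param clamp Clamp `|r| >= 1` to `1 - 1e-12` instead of erroring.
#' @return `atanh(r)`.
#' @export
#' @examples
#' fisher_z(0.5)        # 0.5 * log(3)
#' tanh(fisher_z(0.8))  # 0.8
fisher_z <- function(r, clamp = FALSE) {
  if (any(!is.finite(r))) stop("non-finite correlation", call. = FALSE)
  out_of_domain <- abs(r) >= 1
  if (any(out_of_domain)) {
    if (!clamp) {
      stop("|r| >= 1 is outside the domain of the Fisher z-transform ",
           "(use clamp = TRUE for degenerate inputs)", call. = FALSE)
    }
    r[out_of_domain] <- sign(r[out_of_domain]) * (1 - 1e-12)
  }
  atanh(r)
}

#' Pearson correlation with profile preconditions
#'
#' Thin validating wrapper around [stats::cor()]: requires at least 3 pairs
#' and non-constant coordinates (a per-allele correlation on fewer countries
#' is not meaningful).
#'
#' @param x,y Numeric vectors of equal length.
#' @return The product-moment correlation.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance in a coordinate",
         call. = FALSE)
  }
  stats::cor(x, y)
}

#' Coverage filter: alleles reported in enough prevalence countries
#'
#' Retains the alleles whose frequency is reported in at least
#' `min_countries` of the countries that also have a prevalence value.
#' The before/after distinct-allele counts are attached as attribute
#' `coverage_counts`.
#'
#' @param freq An [allele_frequency_table()].
#' @param prev A [prevalence_table()].
#' @param min_countries Minimum country coverage (default 9, the profile's
#'   conservative threshold; must be at least 3 for the downstream
#'   correlations to be defined).
#' @return A filtered `allele_freq_table` (records restricted to prevalence
#'   countries).
#' @export
filter_by_coverage <- function(freq, prev, min_countries = 9L) {
  stopifnot(inherits(freq, "allele_freq_table"),
            inherits(prev, "prevalence_table"))
  if (min_countries < 3L) {
    stop("min_countries must be at least 3", call. = FALSE)
  }
  common <- intersect(unique(freq$country), prev$country)
  if (length(common) == 0L) {
    stop("no countries in common between frequency and prevalence tables",
         call. = FALSE)
  }
  n_before <- length(unique(freq$allele))
  sub <- freq[freq$country %in% common, , drop = FALSE]
  cov <- table(sub$allele)
  keep <- names(cov)[cov >= min_countries]
  out <- sub[sub$allele %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            class = c("allele_freq_table", "data.frame"),
            coverage_counts = c(before = n_before, after = length(keep)))
}

#' Paired (frequency, log prevalence) observations for one allele
#'
#' One pair per country where the allele's frequency is reported AND a
#' prevalence value exists; countries missing either are excluded. The
#' number of pairs is the allele's N in the profile.
#'
#' @param allele Canonical allele name (or anything [parse_hla_allele()]
#'   accepts).
#' @param freq An [allele_frequency_table()].
#' @param prev A [prevalence_table()].
#' @return data.frame with columns `country`, `frequency`, `log_prevalence`.
#' @export
pair_observations <- function(allele, freq, prev) {
  allele <- parse_hla_allele(allele)$allele
  sub <- freq[freq$allele == allele, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("allele not present in frequency table: ", allele, call. = FALSE)
  }
  m <- match(sub$country, prev$country)
  ok <- !is.na(m)
  data.frame(
    country = sub$country[ok],
    frequency = sub$frequency[ok],
    log_prevalence = prev$log_prevalence[m[ok]],
    stringsAsFactors = FALSE
  )
}

# Internal constructor; reorder gives the canonical locus/field layout.
new_hla_profile <- function(df, min_countries, source = NULL,
                            unanalyzable = NULL, reorder = TRUE) {
  if (reorder && nrow(df) > 0L) {
    parsed <- parse_hla_allele(df$allele)
    df <- df[allele_order(parsed$locus, parsed$field1, parsed$field2), ,
             drop = FALSE]
  }
  rownames(df) <- NULL
  structure(df,
            class = c("hla_profile", "data.frame"),
            min_countries = min_countries,
            source = source,
            unanalyzable = unanalyzable)
}

#' Fit a population-level HLA-disease profile
#'
#' The central estimator. For every allele that survives the country
#' coverage filter, the Pearson correlation r between its population
#' frequency and the natural log of percent disease prevalence is computed
#' across the countries reporting that allele, then Fisher z-transformed to
#' r' = atanh(r). Negative r' is read as population-level protection,
#' positive r' as susceptibility. Per-allele N varies because each
#' correlation uses only the countries reporting that allele.
#'
#' Alleles that cannot be analysed (fewer than 3 usable pairs, or constant
#' frequency) are not silently dropped: they are listed, with reasons, in
#' `attr(x, "unanalyzable")`.
#'
#' @param freq An [allele_frequency_table()].
#' @param prev A [prevalence_table()].
#' @param min_countries Country coverage threshold (default 9).
#' @param clamp Passed to [fisher_z()]; clamps perfect correlations arising
#'   from degenerate (e.g. noiseless synthetic) inputs.
#' @param cor_pvalues If `TRUE`, adds a `p_value` column with the per-allele
#'   two-sided correlation test p (reporting aid only; the profile performs
#'   no per-allele inference).
#' @return An object of class `hla_profile`: a data.frame with columns
#'   `allele`, `locus`, `hla_class`, `n_countries`, `r`, `r_prime`,
#'   `direction`, ordered by locus (A, B, C, DPB1, DQB1, DRB1) and allele
#'   fields. Attributes: `min_countries`, `unanalyzable`, `source`.
#' @seealso [t1d_profile()] for the packaged reference profile,
#'   [profile_stats()] / [summary.hla_profile()] for the inference battery,
#'   [rank_alleles()] for the strongest associations.
#' @export
hla_profile <- function(freq, prev, min_countries = 9L, clamp = FALSE,
                        cor_pvalues = FALSE) {
  kept <- filter_by_coverage(freq, prev, min_countries)
  alleles <- unique(kept$allele)
  rows <- vector("list", length(alleles))
  bad <- character(0)
  for (i in seq_along(alleles)) {
    a <- alleles[i]
    sub <- kept[kept$allele == a, , drop = FALSE]
    m <- match(sub$country, prev$country)
    x <- sub$frequency
    y <- prev$log_prevalence[m]
    if (length(x) < 3L) {
      bad[a] <- "fewer than 3 paired observations"
      next
    }
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      bad[a] <- "zero variance"
      next
    }
    r <- stats::cor(x, y)
    rp <- tryCatch(fisher_z(r, clamp = clamp), error = function(e) NA_real_)
    if (is.na(rp)) {
      bad[a] <- "perfect correlation (|r| = 1); rerun with clamp = TRUE"
      next
    }
    row <- data.frame(
      allele = a, locus = sub$locus[1L], hla_class = sub$hla_class[1L],
      n_countries = length(x), r = r, r_prime = rp,
      direction = if (rp < 0) "protective" else "susceptibility",
      stringsAsFactors = FALSE
    )
    if (cor_pvalues) {
      row$p_value <- stats::cor.test(x, y)$p.value
    }
    rows[[i]] <- row
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    stop("no analyzable alleles after filtering", call. = FALSE)
  }
  df <- do.call(rbind, rows)
  new_hla_profile(df, min_countries = as.integer(min_countries),
                  source = "fitted", unanalyzable = bad)
}

#' Rank profile entries by strength of association
#'
#' @param profile An `hla_profile`.
#' @param direction `"susceptibility"` (descending r') or `"protective"`
#'   (ascending r').
#' @param k Number of entries to return; larger than the profile returns the
#'   full ordering. Ties are broken by canonical allele order.
#' @return The top-k rows of the profile in the requested order.
#' @export
#' @examples
#' rank_alleles(t1d_profile(), "susceptibility", 5)$allele
rank_alleles <- function(profile,
                         direction = c("susceptibility", "protective"),
                         k = 5L) {
  stopifnot(inherits(profile, "hla_profile"), k >= 1L)
  direction <- match.arg(direction)
  key <- if (direction == "susceptibility") -profile$r_prime
         else profile$r_prime
  # profile rows are already in canonical allele order, so a stable sort on
  # the signed key breaks ties canonically
  ord <- order(key)
  out <- profile[ord[seq_len(min(k, nrow(profile)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.hla_profile <- function(x, n = 10L, ...) {
  src <- attr(x, "source")
  cat("HLA-disease profile: ", nrow(x), " alleles",
      if (!is.null(src)) paste0(" [", src, "]"), "\n", sep = "")
  mc <- attr(x, "min_countries")
  if (!is.null(mc) && !is.na(mc)) {
    cat("  country coverage threshold: >=", mc, "\n")
  }
  if (nrow(x) > 0L) {
    cat("  protective (r' < 0): ", sum(x$r_prime < 0),
        ", susceptibility (r' > 0): ", sum(x$r_prime > 0), "\n", sep = "")
  }
  un <- attr(x, "unanalyzable")
  if (length(un) > 0L) {
    cat("  un-analyzable alleles:", length(un), "\n")
  }
  print(utils::head(as.data.frame(x), n))
  if (nrow(x) > n) cat("... (", nrow(x) - n, " more rows)\n", sep = "")
  invisible(x)
}

#' Profile-level inference battery
#'
#' `summary()` on a fitted or packaged profile runs the full statistics
#' report: sign splits with one-sample proportion z-tests (overall, per
#' class, and for the class-membership split), the one-way ANOVA of r' by
#' sample size N with pairwise group-mean comparisons, the nested
#' class/gene ANOVA, and the |r'| strength t-tests. See [profile_stats()].
#'
#' @param object An `hla_profile`.
#' @param ... Passed to [profile_stats()].
#' @return An `hla_stats_report`.
#' @export
summary.hla_profile <- function(object, ...) {
  profile_stats(object, ...)
}

#' Extract the profile coefficients
#'
#' @param object An `hla_profile`.
#' @param ... Ignored.
#' @return Named numeric vector of r' values (names are allele names).
#' @export
coef.hla_profile <- function(object, ...) {
  stats::setNames(object$r_prime, object$allele)
}

#' Histogram of the profile's r' values
#'
#' @param x An `hla_profile`.
#' @param by_class Overlay separate histograms for class I and II.
#' @param ... Passed to [graphics::hist()].
#' @return `x`, invisibly.
#' @export
plot.hla_profile <- function(x, by_class = FALSE, ...) {
  if (!by_class) {
    graphics::hist(x$r_prime, main = "HLA-disease profile",
                   xlab = "r' (Fisher z-transformed correlation)", ...)
    graphics::abline(v = 0, lty = 2)
  } else {
    op <- graphics::par(mfrow = c(2, 1))
    on.exit(graphics::par(op))
    for (cl in c("I", "II")) {
      graphics::hist(x$r_prime[x$hla_class == cl],
                     main = paste("Class", cl),
                     xlab = "r'", ...)
      graphics::abline(v = 0, lty = 2)
    }
  }
  invisible(x)
}
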