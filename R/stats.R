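# Profile-level inference: sign splits and proportion tests, ANOVA of r' by
# sample size, nested class/gene ANOVA, and |r'| strength t-tests.

#' Sign split of a profile
#'
#' Counts protective (r' < 0) and susceptibility (r' > 0) entries; exact
#' zeros are counted separately (none are expected on real data).
#'
#' @param x An `hla_profile` or a numeric vector of r' values.
#' @return A list of class `sign_summary`: `n_total`, `n_negative`,
#'   `n_positive`, `n_zero`.
#' @export
#' @examples
#' sign_counts(t1d_profile())
sign_counts <- function(x) {
  rp <- if (inherits(x, "hla_profile")) x$r_prime else as.numeric(x)
  if (length(rp) == 0L) stop("empty profile", call. = FALSE)
  structure(list(
    n_total = length(rp),
    n_negative = sum(rp < 0),
    n_positive = sum(rp > 0),
    n_zero = sum(rp == 0)
  ), class = "sign_summary")
}

#' @export
print.sign_summary <- function(x, ...) {
  cat(sprintf("sign split: %d negative (%.1f%%), %d positive (%.1f%%)",
              x$n_negative, 100 * x$n_negative / x$n_total,
              x$n_positive, 100 * x$n_positive / x$n_total))
  if (x$n_zero > 0) cat(",", x$n_zero, "zero")
  cat(" of", x$n_total, "\n")
  invisible(x)
}

#' One-sample proportion z-test (normal approximation)
#'
#' `z = (k - n * p0) / sqrt(n * p0 * (1 - p0))` with no continuity
#' correction, reported as `|z|` with two-sided `p = 2 * (1 - pnorm(|z|))`.
#' This is the statistic printed for every sign-split comparison in a
#' profile report; [binom_exact_test()] is the exact alternative.
#'
#' @param k Observed count of successes.
#' @param n Number of trials.
#' @param p0 Null proportion (default 0.5).
#' @return An object of class `htest` with the z statistic and two-sided p.
#' @export
#' @examples
#' prop_z_test(70, 127)  # z = 1.154, p = 0.249
prop_z_test <- function(k, n, p0 = 0.5) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (k < 0 || k > n) stop("k must be in [0, n]", call. = FALSE)
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)", call. = FALSE)
  z <- abs(k - n * p0) / sqrt(n * p0 * (1 - p0))
  p <- 2 * stats::pnorm(-z)
  structure(list(
    statistic = c(z = z),
    p.value = p,
    estimate = c(proportion = k / n),
    null.value = c(proportion = p0),
    alternative = "two.sided",
    method = "One-sample proportion z-test (normal approximation, no continuity correction)",
    data.name = sprintf("%d of %d", k, n)
  ), class = "htest")
}

#' Exact two-sided binomial test
#'
#' Exact two-sided p by summing all outcomes with probability less than or
#' equal to that of the observed count under Binomial(n, p0) (the method of
#' [stats::binom.test()], which this wraps).
#'
#' @inheritParams prop_z_test
#' @return An object of class `htest`.
#' @export
binom_exact_test <- function(k, n, p0 = 0.5) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (k < 0 || k > n) stop("k must be in [0, n]", call. = FALSE)
  stats::binom.test(k, n, p = p0, alternative = "two.sided")
}

#' Unpooled (Wald) two-proportion z-test
#'
#' `z = (p1 - p2) / sqrt(p1 (1 - p1) / n1 + p2 (1 - p2) / n2)` with a
#' two-sided normal p-value. The statistic assumes the two samples are
#' independent; it is not valid for complementary proportions of a single
#' sample (use [prop_z_test()] there, which is what profile sign splits
#' report).
#'
#' @param k1,n1 Successes and trials in the first sample.
#' @param k2,n2 Successes and trials in the second sample.
#' @return An object of class `htest`.
#' @export
wald_two_proportion <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("sample sizes must be positive", call. = FALSE)
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) {
    stop("counts must be within [0, n]", call. = FALSE)
  }
  p1 <- k1 / n1
  p2 <- k2 / n2
  se2 <- p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2
  if (se2 == 0) {
    stop("degenerate proportions (both 0 or 1); Wald statistic undefined",
         call. = FALSE)
  }
  z <- (p1 - p2) / sqrt(se2)
  structure(list(
    statistic = c(z = z),
    p.value = 2 * stats::pnorm(-abs(z)),
    estimate = c(proportion1 = p1, proportion2 = p2),
    alternative = "two.sided",
    method = "Wald (unpooled) two-proportion z-test",
    data.name = sprintf("%d/%d vs %d/%d", k1, n1, k2, n2)
  ), class = "htest")
}

#' One-way ANOVA
#'
#' Classical one-way decomposition via [stats::lm()]; for a single factor
#' the F statistic is identical whether the factor is labelled fixed or
#' random.
#'
#' @param values Numeric response.
#' @param groups Grouping labels (coerced to factor).
#' @return List with `statistic` (F), `df` (between, within), `p_value`,
#'   and the full `table` (anova table).
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (length(values) <= nlevels(groups)) {
    stop("need more observations than groups", call. = FALSE)
  }
  if (stats::var(values) == 0) {
    stop("all values identical; F undefined", call. = FALSE)
  }
  tab <- stats::anova(stats::lm(values ~ groups))
  list(
    statistic = tab$`F value`[1L],
    df = c(between = tab$Df[1L], within = tab$Df[2L]),
    p_value = tab$`Pr(>F)`[1L],
    table = tab
  )
}

#' Pairwise comparisons of group means
#'
#' All pairwise mean differences with adjusted p-values; default
#' Bonferroni-adjusted pooled-variance t-tests (via
#' [stats::pairwise.t.test()]).
#'
#' @param values Numeric response.
#' @param groups Grouping labels.
#' @param method P-value adjustment method (see [stats::p.adjust.methods]).
#' @param pool_sd Use a pooled standard deviation across all groups.
#' @return data.frame with columns `group1`, `group2`, `diff` (mean1 -
#'   mean2), `p_value`.
#' @export
pairwise_group_means <- function(values, groups, method = "bonferroni",
                                 pool_sd = TRUE) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  means <- tapply(values, groups, mean)
  pt <- stats::pairwise.t.test(values, groups, p.adjust.method = method,
                               pool.sd = pool_sd)
  pm <- pt$p.value
  out <- do.call(rbind, lapply(rownames(pm), function(g1) {
    cols <- colnames(pm)[!is.na(pm[g1, ])]
    if (length(cols) == 0L) return(NULL)
    data.frame(group1 = g1, group2 = cols,
               diff = unname(means[g1] - means[cols]),
               p_value = unname(pm[g1, cols]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Nested ANOVA of r' by HLA class and gene within class
#'
#' Decomposes r' variation into class (I vs II), gene nested within class
#' (the six loci), and residual sums of squares. The error term for the
#' class effect is configurable: `"residual"` (default) tests class over
#' the residual mean square; `"gene"` tests it over the gene-within-class
#' mean square, the appropriate choice when genes are viewed as a random
#' sample of loci.
#'
#' @param profile An `hla_profile`.
#' @param class_error `"residual"` or `"gene"`.
#' @return List with per-term entries (`class`, `gene_within_class`), each
#'   holding `statistic`, `df`, `p_value`, plus the full `table`.
#' @export
anova_class_gene <- function(profile, class_error = c("residual", "gene")) {
  stopifnot(inherits(profile, "hla_profile"))
  class_error <- match.arg(class_error)
  small <- names(which(table(profile$locus) < 2L))
  if (length(small) > 0L) {
    warning("gene(s) with < 2 entries pooled into the nested term: ",
            paste(small, collapse = ", "), call. = FALSE)
  }
  if (stats::var(profile$r_prime) == 0) {
    stop("all r' values identical; F undefined", call. = FALSE)
  }
  cls <- factor(profile$hla_class)
  gene <- factor(profile$locus)
  tab <- stats::anova(stats::lm(profile$r_prime ~ cls + cls:gene))
  ms <- tab$`Sum Sq` / tab$Df
  df_class <- tab$Df[1L]
  df_gene <- tab$Df[2L]
  df_res <- tab$Df[3L]
  if (class_error == "residual") {
    f_class <- ms[1L] / ms[3L]
    p_class <- stats::pf(f_class, df_class, df_res, lower.tail = FALSE)
    df_class_err <- df_res
  } else {
    f_class <- ms[1L] / ms[2L]
    p_class <- stats::pf(f_class, df_class, df_gene, lower.tail = FALSE)
    df_class_err <- df_gene
  }
  f_gene <- ms[2L] / ms[3L]
  list(
    class = list(statistic = f_class, df = c(df_class, df_class_err),
                 p_value = p_class, error_term = class_error),
    gene_within_class = list(
      statistic = f_gene, df = c(df_gene, df_res),
      p_value = stats::pf(f_gene, df_gene, df_res, lower.tail = FALSE)
    ),
    table = tab
  )
}

#' Strength comparison: |r'| of protective vs susceptibility entries
#'
#' For each HLA class (or each gene), an independent-samples t-test
#' (pooled variance by default) comparing the absolute association
#' strength |r'| between negative (protective) and positive
#' (susceptibility) entries. Cells with fewer than 2 entries of either
#' sign are skipped with a warning.
#'
#' @param profile An `hla_profile`.
#' @param split_by `"class"` or `"gene"`.
#' @param var_equal Pooled-variance t-test (classic independent-samples
#'   form); set `FALSE` for Welch.
#' @return data.frame with columns `group`, `n_negative`, `n_positive`,
#'   `statistic` (t), `df`, `p_value`.
#' @export
strength_ttest <- function(profile, split_by = c("class", "gene"),
                           var_equal = TRUE) {
  stopifnot(inherits(profile, "hla_profile"))
  split_by <- match.arg(split_by)
  key <- if (split_by == "class") profile$hla_class else profile$locus
  rows <- lapply(unique(key), function(g) {
    rp <- profile$r_prime[key == g]
    neg <- abs(rp[rp < 0])
    pos <- abs(rp[rp > 0])
    if (length(neg) < 2L || length(pos) < 2L) {
      warning("skipping ", split_by, " ", g,
              ": fewer than 2 entries of each sign", call. = FALSE)
      return(NULL)
    }
    tt <- stats::t.test(neg, pos, var.equal = var_equal)
    data.frame(group = g, n_negative = length(neg), n_positive = length(pos),
               statistic = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    stop("no ", split_by, " cell has >= 2 entries of each sign",
         call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Standardized report entry.
report_entry <- function(test, statistic = NULL, df = NULL, p_value = NULL,
                         groups = NULL) {
  list(test = test, statistic = statistic, df = df, p_value = p_value,
       groups = groups)
}

#' Full profile statistics report
#'
#' Runs the complete inference battery on a profile, in deterministic
#' order: sign splits with one-sample proportion z-tests (overall, per HLA
#' class, and for the class-membership split of the profile), the one-way
#' ANOVA of r' by sample size N with Bonferroni pairwise group-mean
#' comparisons, the nested class/gene ANOVA, and the |r'| strength t-tests
#' by class and by gene. A failing component is recorded as an `error`
#' entry without aborting the rest.
#'
#' @param profile An `hla_profile`.
#' @param class_error Error term for the class effect in the nested ANOVA
#'   (see [anova_class_gene()]).
#' @return An object of class `hla_stats_report`: a named list of test
#'   entries, each with `test`, `statistic`, `df`, `p_value`, `groups`.
#' @export
#' @examples
#' rep <- profile_stats(t1d_profile())
#' rep$sign_test_overall$statistic
profile_stats <- function(profile, class_error = c("residual", "gene")) {
  stopifnot(inherits(profile, "hla_profile"))
  if (nrow(profile) == 0L) stop("empty profile", call. = FALSE)
  class_error <- match.arg(class_error)
  entries <- list()
  iso <- function(name, expr) {
    entries[[name]] <<- tryCatch(expr, error = function(e) {
      report_entry(test = name, groups = list(error = conditionMessage(e)))
    })
  }

  sc <- sign_counts(profile)
  entries$sign_counts_overall <- report_entry(
    "sign_counts", groups = list(negative = sc$n_negative,
                                 positive = sc$n_positive,
                                 zero = sc$n_zero, total = sc$n_total))
  iso("sign_test_overall", {
    ht <- prop_z_test(sc$n_positive, sc$n_total)
    report_entry("one_sample_proportion_z", unname(ht$statistic), NA,
                 ht$p.value,
                 list(positive = sc$n_positive, total = sc$n_total))
  })

  n_I <- sum(profile$hla_class == "I")
  iso("class_membership_test", {
    ht <- prop_z_test(n_I, nrow(profile))
    report_entry("one_sample_proportion_z", unname(ht$statistic), NA,
                 ht$p.value, list(class_I = n_I, total = nrow(profile)))
  })

  for (cl in c("I", "II")) {
    scc <- sign_counts(profile$r_prime[profile$hla_class == cl])
    entries[[paste0("sign_counts_class_", cl)]] <- report_entry(
      "sign_counts", groups = list(negative = scc$n_negative,
                                   positive = scc$n_positive,
                                   zero = scc$n_zero, total = scc$n_total))
    iso(paste0("sign_test_class_", cl), {
      ht <- prop_z_test(scc$n_positive, scc$n_total)
      report_entry("one_sample_proportion_z", unname(ht$statistic), NA,
                   ht$p.value,
                   list(positive = scc$n_positive, total = scc$n_total))
    })
  }

  iso("wald_protective_by_class", {
    sI <- sign_counts(profile$r_prime[profile$hla_class == "I"])
    sII <- sign_counts(profile$r_prime[profile$hla_class == "II"])
    ht <- wald_two_proportion(sI$n_negative, sI$n_total,
                              sII$n_negative, sII$n_total)
    report_entry("wald_two_proportion", unname(ht$statistic), NA, ht$p.value,
                 list(class_I = sprintf("%d/%d", sI$n_negative, sI$n_total),
                      class_II = sprintf("%d/%d", sII$n_negative,
                                         sII$n_total)))
  })

  iso("anova_by_sample_size", {
    av <- anova_oneway(profile$r_prime, profile$n_countries)
    report_entry("oneway_anova", av$statistic, unname(av$df), av$p_value,
                 list(factor = "n_countries",
                      levels = sort(unique(profile$n_countries))))
  })
  iso("pairwise_by_sample_size", {
    pw <- pairwise_group_means(profile$r_prime, profile$n_countries)
    report_entry("pairwise_t_bonferroni", NA, NA, NA, pw)
  })

  iso("anova_class_gene", {
    ng <- anova_class_gene(profile, class_error = class_error)
    report_entry("nested_anova", NULL, NULL, NULL, list(
      class = list(statistic = ng$class$statistic,
                   df = unname(ng$class$df), p_value = ng$class$p_value,
                   error_term = ng$class$error_term),
      gene_within_class = list(
        statistic = ng$gene_within_class$statistic,
        df = unname(ng$gene_within_class$df),
        p_value = ng$gene_within_class$p_value)
    ))
  })

  iso("strength_by_class", {
    report_entry("strength_ttest", NA, NA, NA,
                 strength_ttest(profile, "class"))
  })
  iso("strength_by_gene", {
    report_entry("strength_ttest", NA, NA, NA,
                 strength_ttest(profile, "gene"))
  })

  structure(entries, class = "hla_stats_report")
}

#' @export
print.hla_stats_report <- function(x, ...) {
  cat("Profile statistics report (", length(x), " entries)\n", sep = "")
  for (nm in names(x)) {
    e <- x[[nm]]
    stat <- e$statistic
    if (!is.null(stat) && length(stat) == 1L && is.finite(stat)) {
      dfs <- if (!is.null(e$df) && all(is.finite(e$df))) {
        paste0(" df=", paste(e$df, collapse = ","))
      } else ""
      cat(sprintf("  %-26s %s = %.3f%s, p = %.3f\n", nm, e$test, stat, dfs,
                  e$p_value))
    } else {
      cat(sprintf("  %-26s [%s]\n", nm, e$test))
    }
  }
  invisible(x)
}
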