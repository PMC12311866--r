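test_that("proportion z-test is symmetric and centred at the null", {
  for (n in c(10, 57, 127)) {
    k <- sample(0:n, 1)
    expect_equal(prop_z_test(k, n)$statistic,
                 prop_z_test(n - k, n)$statistic, tolerance = 1e-12)
  }
  ht <- prop_z_test(50, 100)
  expect_equal(unname(ht$statistic), 0)
  expect_equal(ht$p.value, 1)
  expect_error(prop_z_test(5, 0), "positive")
  expect_error(prop_z_test(11, 10), "k must be")
})

test_that("proportion z matches the closed form (k - n p0)/sqrt(n p0 q0)", {
  set.seed(9)
  for (i in 1:10) {
    n <- sample(20:500, 1)
    k <- sample(0:n, 1)
    p0 <- runif(1, 0.1, 0.9)
    ht <- prop_z_test(k, n, p0)
    z <- abs(k - n * p0) / sqrt(n * p0 * (1 - p0))
    expect_equal(unname(ht$statistic), z, tolerance = 1e-12)
    expect_equal(ht$p.value, 2 * pnorm(-z), tolerance = 1e-12)
  }
})

test_that("exact binomial test matches full-enumeration oracle", {
  expect_equal(binom_exact_test(0, 5, 0.5)$p.value, 0.0625)
  expect_equal(binom_exact_test(5, 10, 0.5)$p.value, 1)
  cases <- list(c(70, 127), c(3, 20), c(18, 25), c(500, 1000))
  for (cs in cases) {
    expect_equal(binom_exact_test(cs[1], cs[2], 0.5)$p.value,
                 binom_enumeration(cs[1], cs[2], 0.5), tolerance = 1e-12)
  }
  expect_equal(binom_exact_test(40, 90, 0.3)$p.value,
               binom_enumeration(40, 90, 0.3), tolerance = 1e-12)
})

test_that("exact binomial p approaches the normal approximation for large n", {
  n <- 1000
  for (k in c(470, 500, 530)) {
    expect_lt(abs(binom_exact_test(k, n, 0.5)$p.value -
                  prop_z_test(k, n, 0.5)$p.value), 0.005)
  }
})

test_that("Wald two-proportion test matches its hand formula", {
  ht <- wald_two_proportion(5, 10, 5, 10)
  expect_equal(unname(ht$statistic), 0)
  expect_equal(ht$p.value, 1)

  k1 <- 31; n1 <- 69; k2 <- 26; n2 <- 58
  p1 <- k1 / n1; p2 <- k2 / n2
  z <- (p1 - p2) / sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  ht <- wald_two_proportion(k1, n1, k2, n2)
  expect_equal(unname(ht$statistic), z, tolerance = 1e-12)

  strong <- wald_two_proportion(9, 10, 1, 10)
  expect_gt(unname(strong$statistic), 0)
  expect_lt(strong$p.value, 0.05)

  expect_error(wald_two_proportion(0, 10, 0, 10), "degenerate")
})

test_that("one-way ANOVA F equals t-squared for two groups", {
  set.seed(17)
  for (i in 1:5) {
    x <- rnorm(12, 0); y <- rnorm(15, 0.5)
    av <- anova_oneway(c(x, y), rep(c("a", "b"), c(12, 15)))
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(av$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(av$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("one-way ANOVA decomposition satisfies SS_total = SS_b + SS_w", {
  set.seed(18)
  vals <- rnorm(60)
  grp <- sample(letters[1:4], 60, replace = TRUE)
  av <- anova_oneway(vals, grp)
  ss_total <- sum((vals - mean(vals))^2)
  expect_equal(sum(av$table$`Sum Sq`), ss_total, tolerance = 1e-10)
  # independent oracle: between/within sums computed by hand
  gm <- tapply(vals, grp, mean)
  gn <- tapply(vals, grp, length)
  ss_b <- sum(gn * (gm - mean(vals))^2)
  f <- (ss_b / (length(gm) - 1)) /
    ((ss_total - ss_b) / (length(vals) - length(gm)))
  expect_equal(av$statistic, f, tolerance = 1e-10)
})

test_that("ANOVA rejects degenerate inputs", {
  expect_error(anova_oneway(rep(1, 10), rep(c("a", "b"), 5)), "identical")
  expect_error(anova_oneway(rnorm(5), rep("a", 5)), "2 groups")
  groups_eq <- rep(c("a", "b", "c"), each = 10)
  vals_eq <- rep(c(0.3, 0.3, 0.3), each = 10) + rnorm(30, sd = 1)
  av <- anova_oneway(vals_eq - ave(vals_eq, groups_eq), groups_eq)
  expect_lt(av$statistic, 1e-20)  # identical group means
})

test_that("pairwise group means flag only genuinely shifted groups", {
  set.seed(19)
  base <- rnorm(40, sd = 0.5)
  vals <- c(base[1:20], base[21:40] + 0, rnorm(20, mean = 3, sd = 0.5))
  grp <- rep(c("g1", "g2", "g3"), each = 20)
  pw <- pairwise_group_means(vals, grp)
  sig <- pw$p_value < 0.05
  involved <- pw$group1 == "g3" | pw$group2 == "g3"
  expect_true(all(sig[involved]))
  expect_false(any(sig[!involved]))

  same <- pairwise_group_means(rep(c(1, 2, 1, 2), 5),
                               rep(c("a", "b"), each = 10))
  expect_equal(same$diff, 0)
  expect_equal(same$p_value, 1)
})

test_that("nested class/gene ANOVA has the right df bookkeeping", {
  ng <- anova_class_gene(t1d_profile())
  expect_equal(unname(ng$class$df), c(1, 121))
  expect_equal(unname(ng$gene_within_class$df), c(4, 121))
  expect_equal(ng$table$Df, c(1, 4, 121))
  ng2 <- anova_class_gene(t1d_profile(), class_error = "gene")
  expect_equal(unname(ng2$class$df), c(1, 4))
})

test_that("nested ANOVA detects a pure class effect", {
  prof <- t1d_profile()
  set.seed(23)
  shifted <- make_profile(prof$allele, prof$n_countries,
                          rnorm(127, sd = 0.2) +
                            ifelse(prof$hla_class == "I", 2, 0))
  ng <- anova_class_gene(shifted)
  expect_gt(ng$class$statistic, 100)
  expect_lt(ng$class$p_value, 1e-10)
  expect_lt(ng$gene_within_class$statistic, 5)
})

test_that("nested ANOVA flags an all-equal profile", {
  prof <- make_profile(t1d_profile()$allele, t1d_profile()$n_countries,
                       rep(0.5, 127))
  expect_error(anova_class_gene(prof), "identical")
})

test_that("strength t-test detects a constructed |r'| shift", {
  prof <- t1d_profile()
  set.seed(29)
  rp <- ifelse(prof$r_prime < 0, prof$r_prime - 1, prof$r_prime)
  shifted <- make_profile(prof$allele, prof$n_countries, rp)
  st <- strength_ttest(shifted, "class")
  expect_true(all(st$p_value < 0.01))
})

test_that("strength t-test skips cells without two entries of each sign", {
  prof <- make_profile(c("A*01:01", "A*02:01", "A*03:01", "A*11:01",
                         "B*07:02", "B*08:01"),
                       rep(9L, 6),
                       c(-0.5, -0.4, 0.3, 0.6, 0.2, 0.4))
  expect_warning(st <- strength_ttest(prof, "gene"), "B")
  expect_equal(st$group, "A")
})

test_that("the full report composes every analysis and isolates failures", {
  rep <- profile_stats(t1d_profile())
  expect_s3_class(rep, "hla_stats_report")
  expect_named(rep, c("sign_counts_overall", "sign_test_overall",
                      "class_membership_test", "sign_counts_class_I",
                      "sign_test_class_I", "sign_counts_class_II",
                      "sign_test_class_II", "wald_protective_by_class",
                      "anova_by_sample_size", "pairwise_by_sample_size",
                      "anova_class_gene", "strength_by_class",
                      "strength_by_gene"))
  expect_error(profile_stats(make_profile(character(0), integer(0),
                                          numeric(0))), "empty")

  # degenerate all-equal profile: ANOVA entries fail, sign counts survive
  flat <- make_profile(t1d_profile()$allele, t1d_profile()$n_countries,
                       rep(0.5, 127))
  rep2 <- suppressWarnings(profile_stats(flat))
  expect_false(is.null(rep2$anova_by_sample_size$groups$error))
  expect_equal(rep2$sign_counts_overall$groups$positive, 127)
})
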