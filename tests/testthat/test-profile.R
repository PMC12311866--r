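test_that("fisher_z is odd, strictly increasing, and inverts through tanh", {
  r <- seq(-0.99, 0.99, by = 0.03)
  expect_equal(fisher_z(-r), -fisher_z(r), tolerance = 1e-12)
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_equal(tanh(fisher_z(r)), r, tolerance = 1e-12)
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3), tolerance = 1e-12)
  expect_equal(fisher_z(tanh(1.031)), 1.031, tolerance = 1e-12)
})

test_that("fisher_z rejects |r| >= 1 unless clamped", {
  expect_error(fisher_z(1), "domain")
  expect_error(fisher_z(-1.2), "domain")
  expect_true(is.finite(fisher_z(1, clamp = TRUE)))
  expect_gt(fisher_z(1, clamp = TRUE), 10)
})

test_that("pearson_r matches the direct sum-formula oracle", {
  set.seed(4)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    expect_equal(pearson_r(x, y), pearson_sum_formula(x, y),
                 tolerance = 1e-12)
  }
  expect_equal(pearson_r(0:2, 0:2), 1)
  expect_equal(pearson_r(c(0, 1, 2), c(1, 0, -1)), -1)
})

test_that("pearson_r is affine-invariant and sign-flips under negation", {
  set.seed(5)
  x <- rnorm(12); y <- rnorm(12)
  r <- pearson_r(x, y)
  expect_equal(pearson_r(3 * x + 7, y), r, tolerance = 1e-12)
  expect_equal(pearson_r(x, 0.1 * y - 2), r, tolerance = 1e-12)
  expect_equal(pearson_r(-2 * x, y), -r, tolerance = 1e-12)
})

test_that("pearson_r enforces its preconditions", {
  expect_error(pearson_r(c(0, 1), c(0, 1)), "3 pairs")
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("coverage filter keeps alleles at the threshold, drops below", {
  countries <- sprintf("c%02d", 1:14)
  rows <- rbind(
    make_freq_df("A*01:01", countries[1:8], 0.1),   # 8 countries: dropped
    make_freq_df("A*02:01", countries[1:9], 0.1),   # 9 countries: kept
    make_freq_df("B*07:02", countries, 0.05)        # 14 countries: kept
  )
  freq <- allele_frequency_table(rows)
  prev <- prevalence_table(make_prev_df(countries, seq(0.2, 0.85, length.out = 14)))
  kept <- filter_by_coverage(freq, prev, 9)
  expect_setequal(unique(kept$allele), c("A*02:01", "B*07:02"))
  cc <- attr(kept, "coverage_counts")
  expect_equal(unname(cc["before"]), 3)
  expect_equal(unname(cc["after"]), 2)
  expect_error(filter_by_coverage(freq, prev, 2), "at least 3")
})

test_that("coverage counts only countries that also have prevalence", {
  countries <- sprintf("c%02d", 1:10)
  freq <- allele_frequency_table(make_freq_df("A*01:01", countries, 0.1))
  prev <- prevalence_table(make_prev_df(countries[1:9],
                                        seq(0.2, 0.8, length.out = 9)))
  # allele reported in 10 countries, prevalence known for 9 of them
  pairs <- pair_observations("A*01:01", freq, prev)
  expect_equal(nrow(pairs), 9L)
  kept10 <- filter_by_coverage(freq, prev, 9)
  expect_equal(length(unique(kept10$allele)), 1L)
  expect_error(
    filter_by_coverage(freq,
                       prevalence_table(make_prev_df("elsewhere", 0.5)), 9),
    "no countries in common")
})

test_that("noiseless log-linear data recovers slope signs exactly", {
  # mutually orthogonal (after centring) frequency columns, so each
  # allele's marginal correlation with the composite log prevalence has
  # exactly the sign of its own slope
  countries <- sprintf("c%02d", 1:10)
  alleles <- c("A*01:01", "B*08:01", "C*07:01", "DQB1*03:02", "DRB1*04:01")
  slopes <- c(-5, 3, -2, 8, 1.5)
  H <- stats::contr.helmert(10)[, 1:5]
  fmat <- apply(H, 2, function(h) 0.15 + 0.1 * h / max(abs(h)))
  freq <- allele_frequency_table(data.frame(
    allele = rep(alleles, each = 10),
    country = rep(countries, 5),
    frequency = as.numeric(fmat)
  ))
  lp <- log(0.4) + as.numeric(fmat %*% slopes)
  prev <- prevalence_table(make_prev_df(countries, exp(lp)))
  prof <- hla_profile(freq, prev, min_countries = 9)
  expect_equal(nrow(prof), 5L)
  expect_equal(sign(prof$r_prime[match(alleles, prof$allele)]),
               sign(slopes))
})

test_that("a constant-frequency allele is flagged un-analyzable, not dropped silently", {
  countries <- sprintf("c%02d", 1:9)
  rows <- rbind(make_freq_df("A*01:01", countries, 0.2),
                make_freq_df("B*07:02", countries,
                             seq(0.05, 0.29, length.out = 9)))
  freq <- allele_frequency_table(rows)
  prev <- prevalence_table(make_prev_df(countries,
                                        seq(0.2, 0.8, length.out = 9)))
  prof <- hla_profile(freq, prev, min_countries = 9)
  expect_equal(prof$allele, "B*07:02")
  un <- attr(prof, "unanalyzable")
  expect_named(un, "A*01:01")
  expect_match(un[["A*01:01"]], "zero variance")
})

test_that("the fitted profile is invariant to input row order", {
  set.seed(13)
  sim <- simulate_hla_dataset(hla_sim_config(noise_sd = 0.2), seed = 21)
  p1 <- hla_profile(sim$frequencies, sim$prevalence, clamp = TRUE)
  shuffled <- as.data.frame(sim$frequencies)
  shuffled <- shuffled[sample(nrow(shuffled)), c("allele", "country",
                                                 "frequency")]
  p2 <- hla_profile(allele_frequency_table(shuffled), sim$prevalence,
                    clamp = TRUE)
  expect_equal(as.data.frame(p1), as.data.frame(p2), tolerance = 1e-12)
})

test_that("synthetic profile at reference-like coverage has 127 entries, N in [9,14]", {
  sim <- simulate_hla_dataset(hla_sim_config(missing_rate = 0.1), seed = 33)
  prof <- hla_profile(sim$frequencies, sim$prevalence, clamp = TRUE)
  expect_lte(nrow(prof), 127L)
  expect_gte(nrow(prof), 100L)
  expect_true(all(prof$n_countries >= 9 & prof$n_countries <= 14))
})

test_that("ranking orders by signed r' and caps at the profile size", {
  prof <- t1d_profile()
  top <- rank_alleles(prof, "susceptibility", 5)
  expect_equal(top$allele, c("A*02:05", "DRB1*12:01", "A*36:01", "A*33:01",
                             "DQB1*03:02"))
  expect_true(all(diff(top$r_prime) <= 0))
  bottom <- rank_alleles(prof, "protective", 5)
  expect_equal(bottom$allele, c("A*01:01", "C*07:04", "C*06:02",
                                "DPB1*13:01", "A*26:01"))
  all_of_it <- rank_alleles(prof, "susceptibility", 1000)
  expect_equal(nrow(all_of_it), 127L)
  expect_true(all(diff(all_of_it$r_prime) <= 0))
})

test_that("profile methods expose coefficients and summaries", {
  prof <- t1d_profile()
  cf <- coef(prof)
  expect_named(cf)
  expect_equal(unname(cf["DQB1*03:02"]), 1.031)
  expect_s3_class(summary(prof), "hla_stats_report")
  expect_output(print(prof), "127 alleles")
})
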