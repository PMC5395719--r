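# cohort filtering, summaries, CIs, age trend, crosstab

make_specimens <- function(n, disease = "D", tmb = 1, age = 60,
                           coverage = 500) {
  data.frame(specimen_id = sprintf("S%04d", seq_len(n)),
             patient_id = sprintf("P%04d", seq_len(n)), disease = disease,
             age = age, sex = "female", median_coverage = coverage,
             tmb = tmb, stringsAsFactors = FALSE)
}

test_that("filter_cohort drops duplicates then low coverage, idempotently", {
  sp <- make_specimens(4)
  sp$patient_id[2] <- sp$patient_id[1]
  sp$median_coverage <- c(500, 500, 299, 300)
  out <- filter_cohort(sp)
  expect_equal(out$specimens$specimen_id, c("S0001", "S0004"))
  expect_equal(out$excluded, c(duplicate = 1L, low_coverage = 1L))
  again <- filter_cohort(out$specimens)
  expect_identical(again$specimens, out$specimens)
  expect_equal(sum(again$excluded), 0L)
  empty <- filter_cohort(sp[0, ])
  expect_equal(nrow(empty$specimens), 0L)
  expect_equal(sum(empty$excluded), 0L)
})

test_that("tally_percent reproduces printed count-pair percentages", {
  expect_equal(tally_percent(173, 1731), 10.0)
  expect_equal(tally_percent(39, 203, digits = 0), 19)
  expect_equal(tally_percent(858, 6348), 13.5)
  expect_equal(tally_percent(191, 92438), 0.2)
  expect_equal(tally_percent(4, 50), 8.0)
  expect_error(tally_percent(5, 4), "k <= n")
})

test_that("percentages round-trip from stored (k, n) pairs", {
  set.seed(1)
  for (i in 1:50) {
    n <- sample(1:5000, 1)
    k <- sample(0:n, 1)
    shown <- tally_percent(k, n)
    expect_identical(tally_percent(k, n), shown)
    expect_lte(abs(shown - 100 * k / n), 0.05 + 1e-12)
  }
})

test_that("Wilson interval matches prop.test and printed bounds", {
  ci <- binomial_ci(4, 50)
  expect_equal(ci[["high"]], 18.8, tolerance = 0.05)
  # oracle: score interval without continuity correction
  for (kn in list(c(0, 10), c(4, 50), c(25, 40), c(173, 1731))) {
    ours <- binomial_ci(kn[1], kn[2])
    pt <- 100 * prop.test(kn[1], kn[2], correct = FALSE)$conf.int
    expect_equal(unname(ours), as.numeric(pt), tolerance = 1e-8)
  }
  expect_equal(binomial_ci(0, 10)[["low"]], 0)
  expect_equal(binomial_ci(10, 10)[["high"]], 100)
  expect_equal(unname(binomial_ci(3, 10, level = 1)), c(0, 100))
  expect_error(binomial_ci(5, 4), "k <= n")
})

test_that("disease_summary applies min_n and matches a sort-based oracle", {
  set.seed(2)
  sp <- rbind(make_specimens(80, disease = "big",
                             tmb = round(rexp(80, 1 / 8), 3)),
              make_specimens(10, disease = "small", tmb = 5))
  out <- disease_summary(sp, high_threshold = 20, min_n = 50)
  expect_equal(out$disease, "big")
  x <- sort(sp$tmb[sp$disease == "big"])
  # type-7 quantile oracle by direct interpolation
  q7 <- function(p) {
    h <- (length(x) - 1) * p + 1
    x[floor(h)] + (h - floor(h)) * (x[ceiling(h)] - x[floor(h)])
  }
  expect_equal(out$median_tmb, q7(0.5))
  expect_equal(out$q25, q7(0.25))
  expect_equal(out$q75, q7(0.75))
  k <- sum(x > 20)
  expect_equal(out$pct_high, 100 * k / 80)
  expect_true(out$ci_low <= out$pct_high && out$pct_high <= out$ci_high)
})

test_that("disease_summary boundary fractions hit 0 and 100", {
  sp <- rbind(make_specimens(60, disease = "low", tmb = 1),
              make_specimens(60, disease = "high", tmb = 50))
  out <- disease_summary(sp)
  expect_equal(out$pct_high[out$disease == "low"], 0)
  expect_equal(out$ci_low[out$disease == "low"], 0)
  expect_equal(out$pct_high[out$disease == "high"], 100)
  expect_equal(out$ci_high[out$disease == "high"], 100)
})

test_that("age_trend recovers a constructed slope exactly", {
  sp <- make_specimens(100)
  sp$age <- seq(10, 90, length.out = 100)
  sp$tmb <- 10^(0.3 + log10(2.4) / 80 * sp$age)
  tr <- suppressWarnings(age_trend(sp))   # noiseless: perfect-fit warning
  expect_equal(tr$fold_10_90, 2.4, tolerance = 1e-10)
  sp$tmb <- rep(3, 100)
  expect_equal(suppressWarnings(age_trend(sp))$fold_10_90, 1.0)
  sp$age <- 50
  expect_error(age_trend(sp), "distinct ages")
})

test_that("msi crosstab reports conditionals and undefined cases", {
  sp <- make_specimens(100)
  sp$tmb <- c(rep(50, 20), rep(1, 80))
  sp$msi_call <- c(rep("MSI-H", 20), rep("MSS", 80))
  ct <- msi_tmb_crosstab(sp)
  expect_equal(ct$p_high_given_msih, 1.0)
  expect_equal(ct$p_ge_thr_given_msih, 1.0)
  expect_equal(ct$p_msih_given_high, 1.0)
  sp$msi_call <- "MSS"
  ct2 <- msi_tmb_crosstab(sp)
  expect_true(is.na(ct2$p_high_given_msih))
  expect_false(ct2$defined[["msih"]])
})

test_that("MSI->high-TMB coupling gives the paper-shaped asymmetry", {
  # unstable specimens get >= 10x TMB; many stable specimens are high-TMB
  # for other reasons, so P(TMB >= 10 | MSI-H) > P(MSI-H | TMB > 20)
  cfg <- cohort_config(n_specimens = 2000, msi_high_rate = 0.1, seed = 17)
  coh <- generate_cohort(cfg, include_variants = FALSE,
                         include_msi = FALSE)
  tr <- coh$ground_truth$specimens
  sp <- coh$specimens
  sp$tmb <- tr$true_tmb
  sp$msi_call <- ifelse(tr$msi_truth == "unstable", "MSI-H", "MSS")
  ct <- msi_tmb_crosstab(sp)
  expect_gt(ct$p_ge_thr_given_msih, ct$p_msih_given_high)
  expect_gt(ct$p_ge_thr_given_msih, 0.9)
})

test_that("explained_fraction reproduces worked arithmetic", {
  sp <- make_specimens(6348, tmb = 50)
  driver <- seq_len(6348) <= 858
  ef <- explained_fraction(sp, driver)
  expect_equal(tally_percent(ef$k, ef$n), 13.5)
  expect_equal(explained_fraction(sp, rep(FALSE, 6348))$percent, 0)
  expect_equal(explained_fraction(sp, rep(TRUE, 6348))$percent, 100)
  low <- make_specimens(10, tmb = 1)
  expect_false(explained_fraction(low, rep(TRUE, 10))$defined)
})
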