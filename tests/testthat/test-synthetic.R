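test_that("exposure marginals reproduce the published medians and ranges", {
  marg <- list(pm25 = c(min = 8.9, median = 13.0, max = 14.1),
               so2  = c(min = 2.1, median = 2.8,  max = 5.9),
               nox  = c(min = 2.5, median = 34.4, max = 45.4))
  ex <- sample_exposures(1e5, marg, default_exposure_correlations(), 1)
  expect_equal(median(ex$pm25), 13.0, tolerance = 0.1)
  expect_equal(median(ex$so2), 2.8, tolerance = 0.1)
  expect_equal(median(ex$nox), 34.4, tolerance = 0.3)
  for (p in names(marg)) {
    expect_gte(min(ex[[p]]), marg[[p]]["min"])
    expect_lte(max(ex[[p]]), marg[[p]]["max"])
  }
})

test_that("the copula recovers the target rank correlations", {
  ex <- sample_exposures(1e5, list(
    pm25 = c(min = 8.9, median = 13.0, max = 14.1),
    so2  = c(min = 2.1, median = 2.8,  max = 5.9),
    nox  = c(min = 2.5, median = 34.4, max = 45.4)),
    default_exposure_correlations(), 42)
  sp <- cor(ex, method = "spearman")
  expect_lt(max(abs(sp - default_exposure_correlations())), 0.03)
})

test_that("identity correlation gives independent pollutants", {
  id3 <- diag(3)
  dimnames(id3) <- list(c("pm25", "so2", "nox"), c("pm25", "so2", "nox"))
  ex <- sample_exposures(1e5, list(
    pm25 = c(min = 0, median = 0.5, max = 1),
    so2 = c(min = 0, median = 0.5, max = 1),
    nox = c(min = 0, median = 0.5, max = 1)), id3, 7)
  cc <- cor(ex)
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.02)
})

test_that("exposure sampling is deterministic and validates inputs", {
  marg <- list(pm25 = c(min = 0, median = 0.4, max = 1))
  one <- matrix(1, 1, 1, dimnames = list("pm25", "pm25"))
  expect_identical(sample_exposures(100, marg, one, 5),
                   sample_exposures(100, marg, one, 5))
  bad <- matrix(c(1, 0.99, 0.99, 0.99, 1, -0.99, 0.99, -0.99, 1), 3,
                dimnames = list(c("pm25", "so2", "nox"),
                                c("pm25", "so2", "nox")))
  expect_error(sample_exposures(10, list(
    pm25 = c(min = 0, median = 0.5, max = 1),
    so2 = c(min = 0, median = 0.5, max = 1),
    nox = c(min = 0, median = 0.5, max = 1)), bad, 1),
    "positive-definite")
  expect_error(
    sample_exposures(10, list(pm25 = c(min = 2, median = 2, max = 2)),
                     one, 1), "min >= max")
})

test_that("exclusion flags have exact counts and conserve records", {
  cfg <- generator_config(seed = 1)
  co <- data.frame(gestational_age = runif(996, 37, 42),
                   pb = 0L)
  flagged <- assign_exclusion_flags(co, cfg$exclusion_counts, 11)
  tab <- table(flagged$exclusion_flag)
  expect_equal(unname(tab[["none"]]), 656)
  expect_equal(sum(tab) - tab[["none"]], 340)
  for (r in names(cfg$exclusion_counts))
    expect_equal(unname(tab[[r]]), unname(cfg$exclusion_counts[[r]]))
  # postdate rows are made consistent with the rule they represent
  expect_true(all(flagged$gestational_age[
    flagged$exclusion_flag == "postdate"] > 42))
})

test_that("degenerate exclusion counts behave at the boundaries", {
  co <- data.frame(gestational_age = runif(50, 37, 42))
  none <- assign_exclusion_flags(co, c(relocated = 0L), 1)
  expect_true(all(none$exclusion_flag == "none"))
  all_flagged <- assign_exclusion_flags(co, c(relocated = 50L), 1)
  expect_true(all(all_flagged$exclusion_flag == "relocated"))
  expect_error(assign_exclusion_flags(co, c(relocated = 51L), 1), "exceed")
})

test_that("null structural model reproduces the target prevalence", {
  # all slopes zero, intercept set to cloglog(113/656): the drawn
  # prevalence must sit within 3 binomial SEs over 200 cohort-sized draws
  lk <- bernoulli_link("cloglog")
  target <- 113 / 656
  spec <- path_model_spec(list(pb = ~ pm25), link = "cloglog")
  cfg <- generator_config(
    spec = spec,
    true_coefficients = list(
      pb = c("(Intercept)" = lk$linkfun(target), pm25 = 0)),
    exposure_marginals = list(pm25 = c(min = 0, median = 0.5, max = 1)),
    exposure_correlations = matrix(1, 1, 1,
                                   dimnames = list("pm25", "pm25")),
    seed = 5)
  n <- 656 * 200
  co <- simulate_cohort(cfg, n = n, exclusions = FALSE)
  se <- sqrt(target * (1 - target) / n)
  expect_lt(abs(mean(co$pb) - target), 3 * se)
})

test_that("zero mediator and pollutant paths give uncorrelated outcomes", {
  spec <- two_eq_spec()
  cfg <- generator_config(
    spec = spec,
    true_coefficients = list(pb = c(pm25 = 0), lbw = c(pb = 0, pm25 = 0.3)),
    exposure_marginals = list(pm25 = c(min = -2, median = 0, max = 2)),
    exposure_correlations = matrix(1, 1, 1,
                                   dimnames = list("pm25", "pm25")),
    seed = 9)
  co <- simulate_cohort(cfg, n = 40000, exclusions = FALSE)
  r <- cor(co$pb, co$lbw)
  expect_lt(abs(r), 3 / sqrt(nrow(co)))
})

test_that("default truth reproduces the implied outcome prevalences", {
  cfg <- generator_config(seed = 21)
  n <- 656 * 200
  co <- simulate_cohort(cfg, n = n, exclusions = FALSE)
  targets <- c(pb = 113 / 656, lbw = 93 / 656, sga = 72 / 656)
  for (out in names(targets)) {
    se <- sqrt(targets[out] * (1 - targets[out]) / n)
    # binomial SE plus the calibration's own Monte-Carlo margin
    expect_lt(abs(mean(co[[out]]) - targets[out]), 3 * se + 0.003)
  }
})

test_that("missingness injection masks at the requested rate, MCAR", {
  cfg <- generator_config(seed = 2)
  co <- simulate_cohort(cfg, n = 1e4, exclusions = FALSE)
  no_miss <- inject_missingness(co, numeric(0), 1)
  expect_false(anyNA(no_miss))
  masked <- inject_missingness(co, c(bmi_t1 = 0.1), 1)
  expect_lt(abs(mean(is.na(masked$bmi_t1)) - 0.1), 0.01)
  expect_identical(inject_missingness(co, c(bmi_t1 = 0.1), 7),
                   inject_missingness(co, c(bmi_t1 = 0.1), 7))
  expect_error(inject_missingness(co, c(pb = 0.1), 1), "may not be masked")
  expect_error(inject_missingness(co, c(bmi_t1 = 1), 1), "rates")
  mar <- inject_missingness(co, c(bmi_t1 = 0.1), 3, mechanism = "mar")
  expect_gt(mean(is.na(mar$bmi_t1[co$low_income == 1])),
            mean(is.na(mar$bmi_t1[co$low_income == 0])))
})

test_that("the generator is bit-reproducible and writes provenance", {
  cfg <- generator_config(seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  expect_equal(attr(a, "seed"), 77)
  tmp <- tempfile(fileext = ".csv")
  write_cohort(a, tmp)
  expect_true(any(grepl("^# seed: 77", readLines(tmp, n = 3))))
  back <- read_cohort(tmp)
  expect_equal(nrow(back), nrow(a))
  expect_equal(back$pm25, a$pm25, tolerance = 1e-12)
  expect_true(file.exists(paste0(tmp, ".schema.json")))
  unlink(c(tmp, paste0(tmp, ".schema.json")))
})

test_that("generator configuration rejects inconsistent inputs", {
  expect_error(generator_config(exposure_marginals = list(
    pm25 = c(min = 5, median = 3, max = 10),
    so2 = c(min = 2.1, median = 2.8, max = 5.9),
    nox = c(min = 2.5, median = 34.4, max = 45.4))), "min <= median")
  expect_error(generator_config(missingness_rates = c(bmi_t1 = 1.2)),
               "\\[0, 1\\)")
  expect_error(generator_config(n_enrolled = 100), "exceed")
  bad <- default_exposure_correlations(); bad[1, 2] <- 0.2  # asymmetric
  expect_error(generator_config(exposure_correlations = bad), "symmetric")
})

test_that("parameter recovery: unbiased estimates with nominal coverage", {
  # scaled-down replicate of the full calibration study (the acceptance
  # suite runs it at 200 x 5000)
  rs <- recovery_study(n_reps = 40, n = 3000, seed = 4)
  expect_equal(rs$failed, 0)
  expect_lt(max(abs(rs$bias)), 0.05)
  expect_gt(rs$overall_coverage, 0.90)
  expect_lt(rs$overall_coverage, 0.99)
})
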