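test_that("path enumeration finds the direct edge and the mediated path", {
  spec <- default_model_spec()
  p <- enumerate_paths(spec, "pm25", "lbw")
  expect_equal(p$direct, c("pm25", "lbw"))
  expect_equal(length(p$indirect), 1)
  expect_equal(p$indirect[[1]], c("pm25", "pb", "lbw"))
})

test_that("an exposure absent from the mediator equation has no indirect path", {
  spec <- path_model_spec(list(pb = ~ pm25, lbw = ~ pb + so2),
                          link = "cloglog")
  p <- enumerate_paths(spec, "so2", "lbw")
  expect_equal(p$direct, c("so2", "lbw"))
  expect_equal(length(p$indirect), 0)
  # no path at all: empty decomposition, not an error
  p2 <- enumerate_paths(spec, "so2", "pb")
  expect_null(p2$direct)
  expect_equal(length(p2$indirect), 0)
})

test_that("multi-mediator chains and diamonds enumerate exhaustively", {
  chain <- path_model_spec(list(m1 = ~ x, m2 = ~ m1, m3 = ~ m2,
                                y = ~ m3 + x), link = "logit")
  p <- enumerate_paths(chain, "x", "y")
  expect_equal(p$indirect, list(c("x", "m1", "m2", "m3", "y")))
  diamond <- path_model_spec(list(m1 = ~ x, m2 = ~ x, y = ~ m1 + m2 + x),
                             link = "logit")
  pd <- enumerate_paths(diamond, "x", "y")
  expect_equal(length(pd$indirect), 2)
  expect_setequal(vapply(pd$indirect, paste, "", collapse = ">"),
                  c("x>m1>y", "x>m2>y"))
})

test_that("decomposition arithmetic: products, sums, additivity", {
  spec <- two_eq_spec()
  fit <- fake_system_fit(c("pb.(Intercept)" = -2, "pb.pm25" = 0.5,
                           "lbw.(Intercept)" = -2, "lbw.pb" = 0.4,
                           "lbw.pm25" = 0.1), spec = spec)
  d <- decompose_effects(fit, "pm25", "lbw")
  expect_equal(d$estimate[d$effect == "direct"], 0.1)
  expect_equal(d$estimate[d$effect == "indirect_total"], 0.2)
  expect_equal(d$estimate[d$effect == "total"], 0.3)
  # additivity is exact, not approximate
  expect_identical(d$estimate[d$effect == "total"],
                   d$estimate[d$effect == "direct"] +
                     d$estimate[d$effect == "indirect_total"])
  # zero covariance collapses every interval to its point
  expect_true(all(d$lower == d$estimate & d$upper == d$estimate))
  expect_equal(d$aor, exp(d$estimate))
})

test_that("a zero mediator edge nullifies the indirect effect", {
  spec <- two_eq_spec()
  fit <- fake_system_fit(c("pb.(Intercept)" = -2, "pb.pm25" = 0.5,
                           "lbw.(Intercept)" = -2, "lbw.pb" = 0,
                           "lbw.pm25" = 0.1), spec = spec)
  d <- decompose_effects(fit, "pm25", "lbw")
  expect_equal(d$estimate[d$effect == "indirect_total"], 0)
  expect_equal(d$estimate[d$effect == "total"],
               d$estimate[d$effect == "direct"])
})

test_that("sign propagation: all-positive edges give positive indirects", {
  spec <- path_model_spec(list(m1 = ~ x, m2 = ~ m1, y = ~ m2 + x),
                          link = "logit")
  for (s in 1:5) {
    set.seed(s)
    b <- abs(rnorm(5)) + 0.01
    fit <- fake_system_fit(c("m1.(Intercept)" = 0, "m1.x" = b[1],
                             "m2.(Intercept)" = 0, "m2.m1" = b[2],
                             "y.(Intercept)" = 0, "y.m2" = b[3],
                             "y.x" = b[4]), spec = spec)
    d <- decompose_effects(fit, "x", "y")
    expect_gt(d$estimate[d$effect == "indirect_total"], 0)
  }
})

test_that("an edge missing from the fit is treated as zero with a notice", {
  spec <- path_model_spec(list(pb = ~ so2, lbw = ~ pb + pm25 + so2),
                          link = "cloglog")
  fit <- fake_system_fit(c("pb.(Intercept)" = -2, "pb.so2" = 0.3,
                           "lbw.(Intercept)" = -2, "lbw.pb" = 0.4,
                           "lbw.so2" = 0.1), spec = spec)
  expect_message(d <- decompose_effects(fit, "pm25", "lbw"), "absent")
  expect_equal(d$estimate[d$effect == "direct"], 0)
})

test_that("delta method: linear forms are exact, zero gradients warn", {
  v <- matrix(c(0.04, 0.01, 0.01, 0.09), 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  fit <- list(coefficients = c(a = 1, b = 2), vcov = v)
  cc <- c(2, -1)
  res <- delta_method_ci(fit, function(beta) sum(cc * beta))
  expect_equal(res$point, 0)
  expect_equal(res$se, sqrt(drop(t(cc) %*% v %*% cc)), tolerance = 1e-6)
  # product with zero variance: zero-width interval
  fit0 <- list(coefficients = c(a = 1.5, b = 2), vcov = 0 * v)
  expect_error(delta_method_ci(fit0, function(beta) beta["a"] * beta["b"]),
               "singular")
  # constant expression: zero gradient warning, interval collapses
  res0 <- suppressWarnings(delta_method_ci(fit, function(beta) 5))
  expect_equal(res0$lower, 5)
  expect_equal(res0$upper, 5)
  expect_warning(delta_method_ci(fit, function(beta) 5), "zero gradient")
})

test_that("delta method on a fitted product matches its analytic gradient", {
  cfg <- mediation_config(seed = 61)
  co <- simulate_cohort(cfg, n = 1500, exclusions = FALSE)
  fit <- fit_system(two_eq_spec(), co)
  expr <- function(b) b[["pb.pm25"]] * b[["lbw.pb"]]
  fd <- delta_method_ci(fit, expr)
  a <- fit$coefficients[["pb.pm25"]]; b <- fit$coefficients[["lbw.pb"]]
  va <- fit$vcov["pb.pm25", "pb.pm25"]; vb <- fit$vcov["lbw.pb", "lbw.pb"]
  expect_equal(fd$se, sqrt(b^2 * va + a^2 * vb), tolerance = 1e-4)
  # the decomposition's indirect CI uses the same delta machinery
  d <- decompose_effects(fit, "pm25", "lbw")
  expect_equal(d$se[d$effect == "indirect_total"], fd$se, tolerance = 1e-6)
})

test_that("the indirect-effect estimator is unbiased for the true product", {
  spec <- two_eq_spec()
  cfg <- mediation_config(seed = 65)
  ind <- numeric(200)
  for (r in 1:200) {
    co <- simulate_cohort(cfg, n = 5000, exclusions = FALSE,
                          seed = 100000 + r)
    f <- fit_system(spec, co)
    ind[r] <- f$coefficients[["pb.pm25"]] * f$coefficients[["lbw.pb"]]
  }
  expect_lt(abs(mean(ind) - 0.3 * 0.5), 0.01)
})

test_that("bootstrap intervals are reproducible and sane", {
  cfg <- mediation_config(seed = 63)
  co <- simulate_cohort(cfg, n = 400, exclusions = FALSE)
  spec <- two_eq_spec()
  expr <- function(b) b[["pb.pm25"]] * b[["lbw.pb"]]
  b1 <- bootstrap_ci(spec, co, expr, B = 200, seed = 9)
  b2 <- bootstrap_ci(spec, co, expr, B = 200, seed = 9)
  expect_identical(b1, b2)
  expect_lte(b1$lower, b1$point + 1e-8)
  expect_gte(b1$upper, b1$point - 1e-8)
  expect_error(bootstrap_ci(spec, co, expr, B = 100, seed = 1), "200")
  expect_error(bootstrap_ci(spec, co, expr, B = 200), "seed")
  # cluster resampling runs and returns an interval
  cl <- rep(1:20, each = 20)
  bc <- bootstrap_ci(spec, co, expr, B = 200, seed = 9, cluster_ids = cl)
  expect_lt(bc$lower, bc$upper)
  # a constant statistic yields a zero-width interval
  b0 <- bootstrap_ci(spec, co, function(b) 1, B = 200, seed = 2)
  expect_equal(b0$lower, b0$upper)
})
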