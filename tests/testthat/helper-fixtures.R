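# Shared fixtures: small specs, configs and deterministic cohorts.

two_eq_spec <- function(link = "cloglog")
  path_model_spec(list(pb = ~ pm25, lbw = ~ pb + pm25), link = link)

three_eq_spec <- function(link = "cloglog")
  path_model_spec(list(pb = ~ pm25, lbw = ~ pb + pm25, sga = ~ pb + pm25),
                  link = link)

# single-exposure generator with the worked mediation truth
# a = 0.3 (pm25 -> pb), b = 0.5 (pb -> lbw), direct = 0.2
mediation_config <- function(seed = 3, b = 0.5)
  generator_config(
    spec = two_eq_spec(),
    true_coefficients = list(pb = c(pm25 = 0.3),
                             lbw = c(pb = b, pm25 = 0.2)),
    exposure_marginals = list(pm25 = c(min = -2, median = 0, max = 2)),
    exposure_correlations = matrix(1, 1, 1,
                                   dimnames = list("pm25", "pm25")),
    seed = seed)

# 20-row fixed fixture for likelihood-oracle tests
glm_fixture <- function() {
  x <- c(-1.9, -1.5, -1.2, -0.9, -0.7, -0.5, -0.3, -0.2, -0.1, 0,
         0.1, 0.2, 0.4, 0.5, 0.7, 0.9, 1.1, 1.4, 1.6, 2.0)
  y <- c(0, 0, 0, 1, 0, 0, 0, 1, 0, 1, 0, 1, 0, 1, 1, 0, 1, 1, 1, 1)
  list(x = cbind("(Intercept)" = 1, slope = x), y = y)
}

# hand-built system fit for arithmetic-only mediation tests
fake_system_fit <- function(coefs, vcov = NULL, spec) {
  if (is.null(vcov))
    vcov <- matrix(0, length(coefs), length(coefs),
                   dimnames = list(names(coefs), names(coefs)))
  structure(list(coefficients = coefs, vcov = vcov, spec = spec,
                 logLik = 0, k = length(coefs), n = 1, fits = list(),
                 link = spec$link, cluster = NULL),
            class = "gsem_fit")
}

# fake per-imputation fit for Rubin-pooling arithmetic
fake_glm_fit <- function(beta, var, n = 100) {
  k <- length(beta)
  vc <- diag(var, k, k)
  dimnames(vc) <- list(names(beta), names(beta))
  structure(list(coefficients = beta, vcov = vc,
                 logLik = 0, n = n, k = k, converged = TRUE),
            class = "bern_glm")
}

# brute-force ML for intercept + one slope via two-stage grid refinement;
# independent of the Newton fitter
grid_ml_two_param <- function(x, y, link, centre = c(0, 0),
                              half_width = 3, rounds = 4, m = 61) {
  lk <- bernoulli_link(link)
  ll <- function(b0, b1) {
    p <- lk$linkinv(b0 + b1 * x)
    sum(y * log(p) + (1 - y) * log(1 - p))
  }
  best <- centre; hw <- half_width
  for (r in seq_len(rounds)) {
    g0 <- seq(best[1] - hw, best[1] + hw, length.out = m)
    g1 <- seq(best[2] - hw, best[2] + hw, length.out = m)
    vals <- outer(g0, g1, Vectorize(ll))
    idx <- arrayInd(which.max(vals), dim(vals))
    best <- c(g0[idx[1]], g1[idx[2]])
    hw <- hw * 2.5 / (m - 1) * 2   # keep a margin around the new centre
  }
  best
}
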