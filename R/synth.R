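#' Configuration of the synthetic birth-cohort generator
#'
#' Bundles everything the generator needs to produce a cohort with known
#' ground truth: enrolment size and exclusion counts matching the study
#' flow (996 enrolled, 340 excluded, 656 analysed), per-pollutant exposure
#' marginals (min, median, max in ug/m3) reproduced by scaled Beta
#' distributions under a Gaussian copula, the structural model and its
#' true coefficients on the linear-predictor scale, an optional shared
#' latent factor, per-variable missingness rates and the root seed.
#'
#' Equation intercepts are calibrated at construction time (deterministic
#' internal computation on a large covariate draw) so that the implied
#' marginal prevalences match `target_prevalences` — by default the case
#' fractions 113/656 (preterm birth), 93/656 (low birthweight) and 72/656
#' (small-for-gestational-age).
#'
#' @param n_enrolled enrolment count.
#' @param exclusion_counts named vector of exclusion reason -> count.
#' @param exposure_marginals named list, each `c(min=, median=, max=)`.
#' @param exposure_correlations 3x3 rank-correlation target (symmetric,
#'   unit diagonal, positive-definite).
#' @param spec the structural [path_model_spec()] the truth lives on.
#' @param true_coefficients named list per outcome of named slope vectors
#'   (intercepts are added by calibration; a supplied `"(Intercept)"`
#'   entry suppresses calibration for that equation).
#' @param link link name for the generating model.
#' @param latent_variance variance of the shared Gaussian factor (0 = none).
#' @param latent_loadings named loadings used when `latent_variance > 0`.
#' @param missingness_rates named per-variable masking rates in [0, 1).
#' @param target_prevalences named outcome prevalences for calibration.
#' @param covariate_params optional override of covariate distributions.
#' @param seed root seed for all generator randomness.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(
    n_enrolled = 996L,
    exclusion_counts = c(multiple_pregnancy = 2L, miscarriage = 55L,
                         stillbirth = 25L, termination = 2L,
                         relocated = 225L, postdate = 31L),
    exposure_marginals = list(
      pm25 = c(min = 8.9, median = 13.0, max = 14.1),
      so2  = c(min = 2.1, median = 2.8,  max = 5.9),
      nox  = c(min = 2.5, median = 34.4, max = 45.4)),
    exposure_correlations = default_exposure_correlations(),
    spec = default_model_spec(link),
    true_coefficients = default_true_coefficients(),
    link = "cloglog",
    latent_variance = 0,
    latent_loadings = c(pb = 1, lbw = 0.8, sga = 0.6),
    missingness_rates = numeric(0),
    target_prevalences = c(pb = 113 / 656, lbw = 93 / 656, sga = 72 / 656),
    covariate_params = default_covariate_params(),
    seed = 20170531L) {
  stopifnot(n_enrolled >= 1, latent_variance >= 0)
  if (any(missingness_rates < 0) || any(missingness_rates >= 1))
    stop("missingness rates must lie in [0, 1)", call. = FALSE)
  check_correlation(exposure_correlations)
  for (nm in names(exposure_marginals)) {
    mg <- exposure_marginals[[nm]]
    if (!(mg["min"] <= mg["median"] && mg["median"] <= mg["max"]))
      stop("marginal for ", nm, " violates min <= median <= max",
           call. = FALSE)
    if (mg["min"] >= mg["max"])
      stop("marginal for ", nm, " has min >= max", call. = FALSE)
  }
  if (sum(exclusion_counts) > n_enrolled)
    stop("exclusion counts exceed enrolment", call. = FALSE)
  cfg <- structure(list(
    n_enrolled = as.integer(n_enrolled),
    exclusion_counts = exclusion_counts,
    n_effective = as.integer(n_enrolled - sum(exclusion_counts)),
    exposure_marginals = exposure_marginals,
    exposure_correlations = exposure_correlations,
    spec = spec, true_coefficients = true_coefficients,
    link = link, latent_variance = latent_variance,
    latent_loadings = latent_loadings,
    missingness_rates = missingness_rates,
    target_prevalences = target_prevalences,
    covariate_params = covariate_params,
    seed = as.integer(seed)
  ), class = "generator_config")
  cfg$true_coefficients <- calibrate_intercepts(cfg)
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config> n_enrolled =", x$n_enrolled,
      " effective =", x$n_effective, " link =", x$link,
      " seed =", x$seed, "\n")
  invisible(x)
}

#' Default exposure rank-correlation structure
#'
#' Modest positive NOx-PM2.5 (0.4) and NOx-SO2 (0.3), weakly negative
#' PM2.5-SO2 (-0.1).  These are package defaults consistent with the
#' qualitative pattern of the study area; the magnitudes are configurable
#' and not published values.
#'
#' @return 3x3 correlation matrix with dimnames pm25/so2/nox.
#' @export
default_exposure_correlations <- function() {
  m <- diag(3)
  dimnames(m) <- list(c("pm25", "so2", "nox"), c("pm25", "so2", "nox"))
  m["pm25", "nox"] <- m["nox", "pm25"] <- 0.4
  m["so2", "nox"] <- m["nox", "so2"] <- 0.3
  m["pm25", "so2"] <- m["so2", "pm25"] <- -0.1
  m
}

check_correlation <- function(m) {
  if (!isSymmetric(unname(m), tol = 1e-10))
    stop("correlation matrix must be symmetric", call. = FALSE)
  if (any(abs(diag(m) - 1) > 1e-12))
    stop("correlation matrix must have unit diagonal", call. = FALSE)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10)
    stop("correlation matrix is not positive-definite (min eigenvalue ",
         format(min(ev), digits = 3), ")", call. = FALSE)
  invisible(TRUE)
}

# Default true slopes: log of the published adjusted odds ratios, rounded
# as printed; mediator paths pb -> lbw / pb -> sga are set to plausibly
# strong values (these edges have no published coefficient).
default_true_coefficients <- function() {
  list(
    pb = c(pm25 = log(1.2), nox = log(0.98), so2 = log(1.2),
           weight_gain = log(0.98), bmi_t1 = log(0.94), hiv = log(1.3),
           smoker = log(1.9), alcohol = log(0.7), educ_primary = log(2.7),
           low_income = 0, unemployed = log(1.7), female = 0),
    lbw = c(pb = 1.5, pm25 = log(1.3), nox = log(0.93), so2 = log(1.1),
            weight_gain = log(0.98), bmi_t1 = log(0.94), syphilis = 0,
            smoker = log(0.7), alcohol = log(1.5), educ_primary = log(1.1),
            low_income = 0, low_se_housing = log(1.7), female = log(0.87)),
    sga = c(pb = 1.2, pm25 = log(1.2), nox = log(0.94), so2 = log(1.1),
            weight_gain = 0, bmi_t1 = log(0.93), syphilis = log(0.9),
            alcohol = log(1.4), phys_exercise = -0.2, female = log(0.9))
  )
}

# Covariate marginals: binary prevalences and truncated-normal parameters
# chosen to be realistic for a low socio-economic urban antenatal cohort.
default_covariate_params <- function() {
  list(
    binary = c(smoker = 0.09, passive_smoker = 0.30, alcohol = 0.09,
               educ_primary = 0.04, unemployed = 0.20, low_income = 0.90,
               low_se_housing = 0.37, multiparous = 0.17, female = 0.48,
               hiv = 0.35, syphilis = 0.07, phys_exercise = 0.44,
               south_durban = 0.665),
    continuous = list(
      maternal_age = c(mean = 26, sd = 5.7, lower = 15, upper = 45),
      bmi_t1 = c(mean = 25.5, sd = 6.0, lower = 15, upper = 50),
      weight_gain = c(mean = 6.4, sd = 6.0, lower = -5, upper = 25),
      height_m = c(mean = 1.60, sd = 0.07, lower = 1.40, upper = 1.85))
  )
}

#' Draw correlated pollutant exposures
#'
#' A Gaussian copula imposes the target rank-correlation structure (the
#' latent Gaussian correlation is `2*sin(pi*rho_s/6)`, the exact
#' Spearman-to-Pearson map for the bivariate normal); marginals are Beta
#' distributions scaled to `[min, max]` with shapes solved so the
#' distribution's median equals the published median.  All draws lie
#' strictly within their ranges.
#'
#' @param n number of records.
#' @param marginals named list of `c(min=, median=, max=)` vectors.
#' @param corr rank-correlation target matrix (rows/cols named as
#'   `marginals`).
#' @param rng an internal seeded stream (or an integer seed).
#' @param concentration total Beta shape `a + b`; controls spread within
#'   the range.
#' @return data frame with one column per pollutant.
#' @export
sample_exposures <- function(n, marginals, corr, rng,
                             concentration = 4) {
  stopifnot(n >= 1)
  if (is.numeric(rng)) rng <- new_rng(rng)
  check_correlation(corr)
  pols <- names(marginals)
  corr <- corr[pols, pols, drop = FALSE]
  latent <- 2 * sin(pi * corr / 6)   # Spearman target -> Gaussian copula
  diag(latent) <- 1
  check_correlation(latent)
  cl <- chol(latent)
  z <- matrix(rnorm_rng(rng, n * length(pols)), n) %*% cl
  u <- stats::pnorm(z)
  out <- data.frame(row.names = seq_len(n))
  for (j in seq_along(pols)) {
    mg <- marginals[[pols[j]]]
    if (mg["min"] >= mg["max"])
      stop("marginal for ", pols[j], " has min >= max", call. = FALSE)
    sh <- beta_shapes_for_median(
      (mg[["median"]] - mg[["min"]]) / (mg[["max"]] - mg[["min"]]),
      concentration)
    out[[pols[j]]] <-
      mg[["min"]] + (mg[["max"]] - mg[["min"]]) *
      stats::qbeta(u[, j], sh[1], sh[2])
  }
  out
}

# shapes (a, b) with a + b = s and Beta median equal to m (0 < m < 1)
beta_shapes_for_median <- function(m, s = 4) {
  m <- min(max(m, 1e-6), 1 - 1e-6)
  f <- function(a) suppressWarnings(stats::qbeta(0.5, a, s - a)) - m
  a <- stats::uniroot(f, c(1e-3, s - 1e-3), tol = 1e-10)$root
  c(a, s - a)
}

# covariates for n mothers; raw weights/height are generated so that the
# derived bmi_t1 / weight_gain reproduce the intended marginals exactly
sample_covariates <- function(n, params, rng) {
  out <- data.frame(row.names = seq_len(n))
  for (nm in names(params$binary))
    out[[nm]] <- rbinom_rng(rng, n, params$binary[[nm]])
  # residential community (clinic catchment): four southern, two northern;
  # the binary south/north label is derived from it
  south <- c("merebank", "bluff", "wentworth", "austerville")
  north <- c("kwamashu", "newlands_east")
  p_south <- params$binary[["south_durban"]]
  comm_prob <- c(rep(p_south / 4, 4), rep((1 - p_south) / 2, 2))
  idx <- sample_int(rng, 6L, n, replace = TRUE, prob = comm_prob)
  out$community <- c(south, north)[idx]
  out$south_durban <- as.integer(idx <= 4)
  for (nm in names(params$continuous)) {
    p <- params$continuous[[nm]]
    out[[nm]] <- rtruncnorm_rng(rng, n, p[["mean"]], p[["sd"]],
                                p[["lower"]], p[["upper"]])
  }
  out$weight_t1 <- out$bmi_t1 * out$height_m^2
  out$weight_t3 <- out$weight_t1 + out$weight_gain
  out
}

# linear predictor of one equation, excluding the intercept
eta_no_intercept <- function(cohort, slopes) {
  eta <- numeric(nrow(cohort))
  for (nm in names(slopes)) {
    if (!nm %in% names(cohort))
      stop("true coefficient refers to missing column '", nm, "'",
           call. = FALSE)
    eta <- eta + slopes[[nm]] * as.numeric(cohort[[nm]])
  }
  eta
}

# deterministic intercept calibration: on a fixed large covariate draw,
# solve mean(invlink(alpha + eta)) = target prevalence, marginalising over
# the mediator analytically and over any latent factor by quadrature
calibrate_intercepts <- function(cfg, n_cal = 50000L) {
  link <- as_bern_link(cfg$link)
  rng <- new_rng(987654321)
  cal <- sample_covariates(n_cal, cfg$covariate_params, rng)
  expo <- sample_exposures(n_cal, cfg$exposure_marginals,
                           cfg$exposure_correlations, rng)
  cal <- cbind(cal, expo)
  gh <- gauss_hermite(15)
  tc <- cfg$true_coefficients
  p_endo <- list()
  for (out in cfg$spec$order) {
    slopes <- tc[[out]]
    if ("(Intercept)" %in% names(slopes)) {
      alpha <- slopes[["(Intercept)"]]
      slopes_no_a <- slopes[setdiff(names(slopes), "(Intercept)")]
    } else {
      alpha <- NA; slopes_no_a <- slopes
    }
    endo_terms <- intersect(names(slopes_no_a), cfg$spec$outcomes)
    exo <- slopes_no_a[setdiff(names(slopes_no_a), endo_terms)]
    eta0 <- eta_no_intercept(cal, exo)
    lam <- if (cfg$latent_variance > 0 &&
               out %in% names(cfg$latent_loadings))
      cfg$latent_loadings[[out]] else 0
    mean_p <- function(a) {
      # marginal over endogenous parents (independence approximation is
      # avoided: parents realised sequentially, so use their calibrated
      # marginal probabilities record-wise) and over the latent factor
      grid <- expand_endo_grid(endo_terms)
      pr <- 0
      for (gi in seq_len(nrow(grid))) {
        eta <- eta0 + a
        w <- rep(1, n_cal)
        for (et in endo_terms) {
          eta <- eta + slopes_no_a[[et]] * grid[gi, et]
          w <- w * (if (grid[gi, et] == 1) p_endo[[et]] else 1 - p_endo[[et]])
        }
        if (lam != 0 && cfg$latent_variance > 0) {
          pk <- 0
          for (k in seq_along(gh$nodes)) {
            u <- sqrt(2 * cfg$latent_variance) * gh$nodes[k]
            pk <- pk + gh$weights[k] / sqrt(pi) * link$linkinv(eta + lam * u)
          }
          pr <- pr + w * pk
        } else {
          pr <- pr + w * link$linkinv(eta)
        }
      }
      mean(pr)
    }
    if (is.na(alpha)) {
      target <- cfg$target_prevalences[[out]]
      alpha <- stats::uniroot(function(a) mean_p(a) - target,
                              c(-15, 8), tol = 1e-9)$root
    }
    p_here <- {
      grid <- expand_endo_grid(endo_terms)
      pr <- 0
      for (gi in seq_len(nrow(grid))) {
        eta <- eta0 + alpha
        w <- rep(1, n_cal)
        for (et in endo_terms) {
          eta <- eta + slopes_no_a[[et]] * grid[gi, et]
          w <- w * (if (grid[gi, et] == 1) p_endo[[et]] else 1 - p_endo[[et]])
        }
        pr <- pr + w * link$linkinv(eta)
      }
      pr
    }
    p_endo[[out]] <- p_here
    tc[[out]] <- c("(Intercept)" = alpha, slopes_no_a)
  }
  tc
}

expand_endo_grid <- function(endo_terms) {
  if (!length(endo_terms)) return(data.frame(row.names = 1))
  g <- expand.grid(rep(list(c(0, 1)), length(endo_terms)))
  names(g) <- endo_terms
  g
}

#' Draw the binary outcomes from the structural model
#'
#' Outcomes are realised in the causal (topological) order of the spec:
#' preterm birth first, then low birthweight and small-for-gestational-age
#' conditional on the realised mediator, so the generator's causal
#' structure matches the mediation model being tested.  If
#' `latent_variance > 0` one shared Gaussian factor enters every linear
#' predictor through the configured loadings.
#'
#' @param cohort data frame holding every predictor the true coefficients
#'   reference.
#' @param config a [generator_config()].
#' @param rng seeded stream or integer seed.
#' @return `cohort` with outcome columns appended.
#' @export
simulate_outcomes <- function(cohort, config, rng) {
  if (is.numeric(rng)) rng <- new_rng(rng)
  if (!config$link %in% link_names())
    stop("link must be one of ", paste(link_names(), collapse = ", "),
         call. = FALSE)
  link <- as_bern_link(config$link)
  n <- nrow(cohort)
  u <- if (config$latent_variance > 0)
    rnorm_rng(rng, n, 0, sqrt(config$latent_variance)) else numeric(n)
  for (out in config$spec$order) {
    slopes <- config$true_coefficients[[out]]
    missing_pred <- setdiff(setdiff(names(slopes), "(Intercept)"),
                            names(cohort))
    if (length(missing_pred))
      stop("predictors missing from cohort: ",
           paste(missing_pred, collapse = ", "), call. = FALSE)
    eta <- slopes[["(Intercept)"]] +
      eta_no_intercept(cohort, slopes[setdiff(names(slopes), "(Intercept)")])
    if (config$latent_variance > 0 &&
        out %in% names(config$latent_loadings))
      eta <- eta + config$latent_loadings[[out]] * u
    cohort[[out]] <- rbinom_rng(rng, n, link$linkinv(eta))
  }
  cohort
}

# gestational age and birthweight consistent with the drawn pb / lbw flags
generate_birth_measures <- function(cohort, rng) {
  n <- nrow(cohort)
  ga <- numeric(n)
  pb <- cohort$pb == 1
  ga[pb] <- rtruncnorm_rng(rng, sum(pb), 34.5, 2.3, 26, 36.99)
  ga[!pb] <- rtruncnorm_rng(rng, sum(!pb), 39.2, 1.3, 37, 42)
  bw_mean <- 3350 - 160 * (40 - ga)
  bw <- numeric(n)
  lbw <- cohort$lbw == 1
  bw[lbw] <- rtruncnorm_rng(rng, sum(lbw), bw_mean[lbw], 380, 500, 2500)
  bw[!lbw] <- rtruncnorm_rng(rng, sum(!lbw), bw_mean[!lbw], 380, 2500.01,
                             5500)
  cohort$gestational_age <- ga
  cohort$birthweight <- bw
  cohort
}

#' Assign exclusion flags with exact counts
#'
#' Flags are placed uniformly at random without replacement, exactly the
#' requested count per reason.  Rows flagged `postdate` have their
#' gestational age overwritten to a value above 42 weeks (and preterm set
#' to 0) so the flag is consistent with the postdate rule.
#'
#' @param cohort data frame.
#' @param counts named vector reason -> count.
#' @param rng seeded stream or integer seed.
#' @return cohort with an `exclusion_flag` factor column
#'   (`"none"` for unflagged rows).
#' @export
assign_exclusion_flags <- function(cohort, counts, rng) {
  if (is.numeric(rng)) rng <- new_rng(rng)
  n <- nrow(cohort)
  if (sum(counts) > n)
    stop("exclusion counts (", sum(counts), ") exceed cohort size (", n,
         ")", call. = FALSE)
  flags <- rep("none", n)
  if (sum(counts) > 0) {
    picked <- sample_int(rng, n, sum(counts))
    reason <- rep(names(counts), counts)
    flags[picked] <- reason
  }
  cohort$exclusion_flag <- factor(flags,
                                  levels = c("none", names(counts)))
  pd <- which(flags == "postdate")
  if (length(pd)) {
    cohort$gestational_age[pd] <- runif_rng(rng, length(pd), 42.05, 43.8)
    if (!is.null(cohort$pb)) cohort$pb[pd] <- 0L
  }
  cohort
}

#' Mask covariate cells at random
#'
#' MCAR by default; the MAR option makes the masking probability depend on
#' observed income (low-income records 1.5 times as likely to be masked,
#' rescaled to preserve the marginal rate).  Outcome and exposure columns
#' are protected and may not be masked.
#'
#' @param cohort data frame.
#' @param rates named per-variable rates in [0, 1).
#' @param rng seeded stream or integer seed.
#' @param mechanism `"mcar"` or `"mar"`.
#' @return cohort with `NA`s injected.
#' @export
inject_missingness <- function(cohort, rates, rng,
                               mechanism = c("mcar", "mar")) {
  mechanism <- match.arg(mechanism)
  if (is.numeric(rng)) rng <- new_rng(rng)
  if (!length(rates)) return(cohort)
  if (any(rates < 0) || any(rates >= 1))
    stop("rates must lie in [0, 1)", call. = FALSE)
  protected <- c("pb", "lbw", "sga", "pm25", "so2", "nox",
                 "gestational_age", "birthweight", "exclusion_flag")
  bad <- intersect(names(rates), protected)
  if (length(bad))
    stop("outcome/exposure columns may not be masked: ",
         paste(bad, collapse = ", "), call. = FALSE)
  n <- nrow(cohort)
  for (nm in names(rates)) {
    if (!nm %in% names(cohort))
      stop("unknown column '", nm, "'", call. = FALSE)
    p <- rep(rates[[nm]], n)
    if (mechanism == "mar" && !is.null(cohort$low_income)) {
      w <- ifelse(cohort$low_income == 1, 1.5, 1)
      p <- rates[[nm]] * w / mean(w)
      p <- pmin(p, 0.99)
    }
    mask <- runif_rng(rng, n) < p
    cohort[[nm]][mask] <- NA
    # keep raw anthropometry consistent with masked derived covariates so
    # re-derivation does not silently resurrect the missing cells
    linked <- c(bmi_t1 = "weight_t1", weight_gain = "weight_t3")
    if (nm %in% names(linked) && linked[[nm]] %in% names(cohort))
      cohort[[linked[[nm]]]][mask] <- NA
  }
  cohort
}

#' Generate a full synthetic cohort
#'
#' End-to-end generator: covariates, copula-correlated exposures, binary
#' outcomes from the structural truth, gestational age and birthweight
#' consistent with the drawn preterm/low-birthweight flags, exclusion
#' flags with exact counts, and (optionally) injected missingness.  All
#' randomness flows from `config$seed`.
#'
#' @param config a [generator_config()].
#' @param n optional override of the enrolment size (used by simulation
#'   studies that want analysis-sized cohorts with no exclusions).
#' @param exclusions set `FALSE` to skip exclusion flags (all rows
#'   eligible).
#' @param seed optional override of `config$seed` (used by replicate
#'   studies that vary the seed while keeping the truth fixed).
#' @return data frame with provenance attributes `seed`, `config_hash`,
#'   `generator_version`.
#' @export
simulate_cohort <- function(config, n = NULL, exclusions = TRUE,
                            seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  seed <- seed %||% config$seed
  rng <- new_rng(seed)
  n <- n %||% config$n_enrolled
  cohort <- sample_covariates(n, config$covariate_params, rng)
  cohort <- cbind(cohort,
                  sample_exposures(n, config$exposure_marginals,
                                   config$exposure_correlations, rng))
  cohort <- simulate_outcomes(cohort, config, rng)
  cohort <- generate_birth_measures(cohort, rng)
  if (exclusions && n >= sum(config$exclusion_counts))
    cohort <- assign_exclusion_flags(cohort, config$exclusion_counts, rng)
  else
    cohort$exclusion_flag <- factor(rep("none", n),
                                    levels = c("none",
                                               names(config$exclusion_counts)))
  if (length(config$missingness_rates))
    cohort <- inject_missingness(cohort, config$missingness_rates, rng)
  attr(cohort, "seed") <- seed
  attr(cohort, "config_hash") <- config_hash(unclass(config))
  attr(cohort, "generator_version") <-
    as.character(utils::packageVersion("gsembirth"))
  cohort
}

cohort_column_dictionary <- function() {
  list(
    pm25 = "annual PM2.5 exposure, ug/m3",
    so2 = "annual SO2 exposure, ug/m3",
    nox = "annual NOx exposure, ug/m3",
    smoker = "maternal smoking, 0/1",
    passive_smoker = "passive tobacco smoke exposure, 0/1",
    alcohol = "alcohol use in pregnancy, 0/1",
    educ_primary = "primary or less maternal education, 0/1",
    unemployed = "maternal unemployment, 0/1",
    low_income = "annual income below US$2000, 0/1",
    low_se_housing = "low socio-economic housing, 0/1",
    multiparous = "parity > 1, 0/1",
    female = "infant sex female, 0/1",
    hiv = "HIV positive, 0/1",
    syphilis = "syphilis positive, 0/1",
    phys_exercise = "physical exercise at least weekly, 0/1",
    south_durban = "residential location south Durban, 0/1",
    community = "residential community (clinic catchment)",
    maternal_age = "maternal age, years",
    bmi_t1 = "first-trimester body-mass index, kg/m2",
    weight_gain = "gestational weight gain (T3 - T1), kg",
    height_m = "maternal height, m",
    weight_t1 = "first-trimester weight, kg",
    weight_t3 = "third-trimester weight, kg",
    pb = "preterm birth (< 37 completed weeks), 0/1",
    lbw = "low birthweight (<= 2500 g), 0/1",
    sga = "small-for-gestational-age, 0/1",
    gestational_age = "gestational age, weeks",
    birthweight = "birthweight, g",
    exclusion_flag = "exclusion reason or 'none'"
  )
}

#' Write / read the cohort CSV dialect
#'
#' The CSV carries provenance header lines prefixed `#` (seed, config
#' hash, generator version) and a sidecar JSON schema
#' (`<path>.schema.json`) documenting each column and its units.
#'
#' @param cohort data frame from [simulate_cohort()] (or compatible).
#' @param path output CSV path.
#' @return `read_cohort` returns the data frame (header comments ignored).
#' @export
write_cohort <- function(cohort, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# seed: ", attr(cohort, "seed") %||% "NA"),
    paste0("# config_hash: ", attr(cohort, "config_hash") %||% "NA"),
    paste0("# generator_version: ",
           attr(cohort, "generator_version") %||% "NA")), con)
  utils::write.csv(cohort, con, row.names = FALSE)
  dict <- cohort_column_dictionary()
  schema <- lapply(names(cohort), function(nm)
    list(name = nm, description = dict[[nm]] %||% "user column"))
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  if ("exclusion_flag" %in% names(out))
    out$exclusion_flag <- factor(out$exclusion_flag)
  out
}
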