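#' Multiple imputation by chained equations
#'
#' Fills missing covariate cells with `m` independent completed datasets.
#' Continuous variables use predictive-mean matching (Bayesian draw of the
#' linear-model coefficients, then a random donor among the `donors`
#' observed records with closest predicted mean); binary variables use
#' logistic-regression draws (coefficients perturbed by their estimated
#' covariance before computing the imputation probability).  The
#' imputation model for each variable includes every other analysis
#' column — outcomes and exposures included, as proper imputation
#' requires.  Visit order is ascending missingness; `cycles` full passes
#' are made per imputation.
#'
#' Outcome columns are never imputed: records missing an outcome should
#' be excluded upstream with a flow-report entry.
#'
#' @param cohort data frame with missing cells in covariates only.
#' @param m number of imputations (default 20).
#' @param seed integer seed.
#' @param cycles chained-equation passes per imputation.
#' @param donors donor-pool size for predictive-mean matching.
#' @param predictors optional character vector restricting the imputation
#'   model's right-hand side.
#' @return object of class `imputation_set`: list of `m` completed data
#'   frames, with attributes `m`, `seed`, `missing_pattern`.
#' @export
impute_chained <- function(cohort, m = 20L, seed, cycles = 10L,
                           donors = 5L, predictors = NULL) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  miss_frac <- vapply(cohort, function(x) mean(is.na(x)), 0)
  if (any(miss_frac == 1))
    stop("column(s) entirely missing: ",
         paste(names(cohort)[miss_frac == 1], collapse = ", "),
         call. = FALSE)
  outcome_cols <- intersect(c("pb", "lbw", "sga"), names(cohort))
  if (any(miss_frac[outcome_cols] > 0))
    stop("outcomes may not be imputed; exclude records missing an outcome",
         call. = FALSE)
  incomplete <- names(miss_frac)[miss_frac > 0]
  numeric_cols <- names(cohort)[vapply(cohort, is.numeric, TRUE)]
  incomplete <- intersect(incomplete, numeric_cols)
  rhs_all <- setdiff(predictors %||% numeric_cols, character(0))

  rng <- new_rng(seed)
  completed <- vector("list", m)
  if (!length(incomplete)) {
    for (i in seq_len(m)) completed[[i]] <- cohort
    return(structure(completed, class = "imputation_set", m = m,
                     seed = seed, missing_pattern = miss_frac))
  }
  # ascending-missingness visit order
  incomplete <- incomplete[order(miss_frac[incomplete])]
  is_binary <- vapply(incomplete, function(v) {
    x <- cohort[[v]]
    all(x[!is.na(x)] %in% c(0, 1))
  }, TRUE)

  for (imp in seq_len(m)) {
    dat <- cohort
    # initial fill: random draws from the observed margin
    for (v in incomplete) {
      nas <- which(is.na(dat[[v]]))
      obs <- dat[[v]][!is.na(dat[[v]])]
      dat[[v]][nas] <- obs[sample_int(rng, length(obs), length(nas),
                                      replace = TRUE)]
    }
    for (cyc in seq_len(cycles)) {
      for (v in incomplete) {
        nas <- which(is.na(cohort[[v]]))
        rhs <- setdiff(rhs_all, v)
        x <- cbind(1, as.matrix(dat[rhs]))
        colnames(x)[1] <- "(Intercept)"
        # drop constant columns within this model
        keep <- c(TRUE, apply(x[, -1, drop = FALSE], 2,
                              function(cc) stats::sd(cc) > 0))
        x <- x[, keep, drop = FALSE]
        obs_rows <- setdiff(seq_len(nrow(dat)), nas)
        if (is_binary[[v]]) {
          dat[[v]][nas] <- draw_binary_imputation(
            x, dat[[v]], obs_rows, nas, rng)
        } else {
          dat[[v]][nas] <- draw_pmm_imputation(
            x, dat[[v]], obs_rows, nas, donors, rng)
        }
      }
    }
    completed[[imp]] <- dat
  }
  structure(completed, class = "imputation_set", m = m, seed = seed,
            missing_pattern = miss_frac)
}

# Bayesian linear model + predictive-mean matching
draw_pmm_imputation <- function(x, y, obs_rows, nas, donors, rng) {
  xo <- x[obs_rows, , drop = FALSE]
  yo <- y[obs_rows]
  xtx <- crossprod(xo)
  # ridge jitter guards near-collinearity in small resamples
  xtx_inv <- solve(xtx + diag(1e-8 * diag(xtx)))
  beta_hat <- drop(xtx_inv %*% crossprod(xo, yo))
  resid <- yo - drop(xo %*% beta_hat)
  df <- max(length(yo) - ncol(xo), 1)
  sigma2 <- sum(resid^2) /
    rng_eval(rng, function() stats::rchisq(1, df))
  l <- chol(xtx_inv)
  beta_star <- beta_hat +
    sqrt(sigma2) * drop(t(l) %*% rnorm_rng(rng, ncol(xo)))
  pred_obs <- drop(xo %*% beta_star)
  pred_mis <- drop(x[nas, , drop = FALSE] %*% beta_star)
  vapply(pred_mis, function(pm) {
    d <- abs(pred_obs - pm)
    pool <- order(d)[seq_len(min(donors, length(d)))]
    yo[pool[sample_int(rng, length(pool), 1L)]]
  }, 0)
}

# logistic fit + coefficient perturbation + Bernoulli draw
draw_binary_imputation <- function(x, y, obs_rows, nas, rng) {
  fit <- tryCatch(
    fit_bernoulli_glm(x[obs_rows, , drop = FALSE], y[obs_rows],
                      link = "logit"),
    error = function(e) NULL)
  if (is.null(fit)) {   # separation etc.: fall back to the observed margin
    p <- mean(y[obs_rows])
    return(rbinom_rng(rng, length(nas), p))
  }
  l <- tryCatch(chol(fit$vcov), error = function(e) NULL)
  beta_star <- if (is.null(l)) fit$coefficients
  else fit$coefficients + drop(t(l) %*% rnorm_rng(rng, fit$k))
  p <- bernoulli_link("logit")$linkinv(
    drop(x[nas, , drop = FALSE] %*% beta_star))
  rbinom_rng(rng, length(nas), p)
}

#' Pool fits across imputations by Rubin's rules
#'
#' Pooled estimate \eqn{\bar Q} = mean of the per-imputation estimates;
#' within-imputation variance \eqn{W} = mean of the per-imputation
#' variances; between-imputation variance \eqn{B} = sample variance of
#' the estimates; total variance \eqn{T = W + (1 + 1/m)B}.  Degrees of
#' freedom follow Barnard-Rubin, with the complete-data df taken as
#' \eqn{n - k} per equation.
#'
#' @param fits list of `gsem_fit` (or `bern_glm`) objects sharing the
#'   same parameter set, one per imputation.
#' @return object of class `pooled_fit`: data frame with `estimate`
#'   (Q-bar), `W`, `B`, `T`, `se`, `df`, plus attributes `m`, `n`, `k`.
#' @export
rubin_pool <- function(fits) {
  m <- length(fits)
  stopifnot(m >= 1)
  par_names <- names(fits[[1]]$coefficients)
  for (f in fits)
    if (!identical(names(f$coefficients), par_names))
      stop("fits have mismatched parameter sets", call. = FALSE)
  est <- do.call(rbind, lapply(fits, function(f) f$coefficients))
  vars <- do.call(rbind, lapply(fits, function(f) diag(f$vcov)))
  qbar <- colMeans(est)
  w <- colMeans(vars)
  if (m == 1) {
    b <- rep(NA_real_, length(qbar)); tot <- w; df <- rep(Inf, length(qbar))
  } else {
    b <- apply(est, 2, stats::var)
    tot <- w + (1 + 1 / m) * b
    n <- fits[[1]]$n; k <- fits[[1]]$k
    nu_com <- max(n - k, 1)
    lambda <- (1 + 1 / m) * b / tot
    nu_old <- ifelse(lambda > 0, (m - 1) / lambda^2, Inf)
    nu_obs <- (nu_com + 1) / (nu_com + 3) * nu_com * (1 - lambda)
    df <- ifelse(is.finite(nu_old), nu_old * nu_obs / (nu_old + nu_obs),
                 nu_obs)
  }
  out <- data.frame(term = par_names, estimate = qbar, W = w, B = b,
                    T = tot, se = sqrt(tot), df = df,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, m = m, n = fits[[1]]$n, k = fits[[1]]$k,
            class = c("pooled_fit", "data.frame"))
}

#' @export
print.pooled_fit <- function(x, ...) {
  cat("Rubin-pooled fit over m =", attr(x, "m"), "imputations\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
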