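#' Gauss-Hermite nodes and weights
#'
#' Physicists' convention: \eqn{\int e^{-t^2} f(t) dt \approx \sum_k w_k
#' f(t_k)}, exact for polynomials of degree up to \eqn{2k - 1}.
#'
#' @param n node count (>= 1).
#' @return list with `nodes`, `weights`.
#' @export
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  gh <- pracma::gaussHermite(as.integer(n))
  list(nodes = gh$x, weights = gh$w)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Mode-curvature adaptive Gauss-Hermite integration
#'
#' Computes \eqn{\log \int \exp h(u)\,du} for a log-concave integrand
#' \eqn{h} (a per-record joint density of data and latent value).  The
#' quadrature grid is recentred at the mode of \eqn{h}, found by
#' safeguarded Newton iteration, and rescaled by
#' \eqn{\hat\sigma = 1/\sqrt{-h''(\hat u)}}:
#' \deqn{\log\int e^{h(u)}du \approx \log(\sqrt2\,\hat\sigma)
#'   + \mathrm{logsumexp}_k\{\log w_k + t_k^2 + h(\hat u + \sqrt2\,
#'   \hat\sigma t_k)\}.}
#' If the mode search does not converge the nonadaptive rule (grid centred
#' at 0 with unit scale) is used with a warning.
#'
#' @param log_f function of a scalar latent value returning the log
#'   integrand; must be log-concave for the adaptive recentring to be valid.
#' @param node_count odd node count (>= 1).
#' @param adaptive set `FALSE` to force the nonadaptive rule.
#' @return scalar: log of the integral.
#' @export
mcagh_integrate <- function(log_f, node_count = 7L, adaptive = TRUE) {
  stopifnot(node_count >= 1)
  gh <- gauss_hermite(node_count)
  dstep <- 1e-5
  h1 <- function(u) (log_f(u + dstep) - log_f(u - dstep)) / (2 * dstep)
  h2 <- function(u) {
    (log_f(u + dstep) - 2 * log_f(u) + log_f(u - dstep)) / dstep^2
  }
  mode <- 0; ok <- FALSE
  if (adaptive) {
    for (it in 1:50) {
      g <- h1(mode); cc <- h2(mode)
      if (!is.finite(g) || !is.finite(cc) || cc >= 0) break
      step <- -g / cc
      # safeguard: halve until the log integrand does not decrease
      lam <- 1
      f0 <- log_f(mode)
      while (lam > 1e-8 && (!is.finite(log_f(mode + lam * step)) ||
                            log_f(mode + lam * step) < f0 - 1e-12))
        lam <- lam / 2
      mode <- mode + lam * step
      if (abs(g) < 1e-9) { ok <- TRUE; break }
    }
    if (!ok && abs(h1(mode)) < 1e-6) ok <- TRUE
  }
  if (adaptive && !ok) {
    warning("mode search did not converge; falling back to nonadaptive rule")
    adaptive <- FALSE
  }
  if (adaptive) {
    sigma <- 1 / sqrt(-h2(mode))
    pts <- mode + sqrt(2) * sigma * gh$nodes
    log(sqrt(2) * sigma) +
      logsumexp(log(gh$weights) + gh$nodes^2 +
                  vapply(pts, log_f, 0))
  } else {
    logsumexp(log(gh$weights) + gh$nodes^2 +
                vapply(gh$nodes, log_f, 0))
  }
}

# Vectorised MCAGH marginal log-likelihood for the one-factor system.
#
# eta: n x J matrix of fixed linear predictors; y: n x J binary matrix;
# lambda: loadings (length J); psi: factor variance; link: bern_link.
# Returns per-record log marginal likelihood (length n).
marginal_loglik_records <- function(eta, y, lambda, psi, link,
                                    node_count = 7L, u_start = NULL,
                                    adaptive = TRUE) {
  n <- nrow(eta); J <- ncol(eta)
  if (psi <= 1e-12) {
    p <- link$linkinv(eta)
    return(rowSums(y * log(p) + (1 - y) * log1p(-p)))
  }
  gh <- gauss_hermite(node_count)
  if (!adaptive) {
    # prior-scaled nonadaptive rule: int N(u;0,psi) g(u) du
    #   ~= sum_k (w_k/sqrt(pi)) g(sqrt(2 psi) t_k)
    acc <- matrix(NA_real_, n, node_count)
    for (k in seq_len(node_count)) {
      uk <- sqrt(2 * psi) * gh$nodes[k]
      cond <- 0
      for (j in seq_len(J)) {
        p <- link$linkinv(eta[, j] + lambda[j] * uk)
        cond <- cond + y[, j] * log(p) + (1 - y[, j]) * log1p(-p)
      }
      acc[, k] <- log(gh$weights[k]) - 0.5 * log(pi) + cond
    }
    m <- apply(acc, 1, max)
    return(m + log(rowSums(exp(acc - m))))
  }
  # per-record log joint h_i(u) and derivatives, vectorised over records
  h_fun <- function(u) {  # u length n
    tot <- stats::dnorm(u, 0, sqrt(psi), log = TRUE)
    for (j in seq_len(J)) {
      p <- link$linkinv(eta[, j] + lambda[j] * u)
      tot <- tot + y[, j] * log(p) + (1 - y[, j]) * log1p(-p)
    }
    tot
  }
  h1_fun <- function(u) {
    g <- -u / psi
    for (j in seq_len(J))
      g <- g + lambda[j] * score_eta(y[, j], eta[, j] + lambda[j] * u, link)
    g
  }
  h2_fun <- function(u) {
    cc <- rep(-1 / psi, n)
    for (j in seq_len(J)) {
      e <- eta[, j] + lambda[j] * u
      p <- link$linkinv(e); v <- p * (1 - p)
      m <- link$mu.eta(e); m2 <- link$mu.eta2(e)
      hj <- m^2 / v - (y[, j] - p) * (m2 / v - m^2 * (1 - 2 * p) / v^2)
      cc <- cc - lambda[j]^2 * hj
    }
    cc
  }
  u <- if (is.null(u_start)) numeric(n) else u_start
  f0 <- h_fun(u)
  for (it in 1:25) {
    g <- h1_fun(u)
    if (max(abs(g)) < 1e-8) break
    cc <- h2_fun(u)
    step <- -g / pmin(cc, -1e-8)
    lam <- rep(1, n)
    for (half in 1:20) {
      f_new <- h_fun(u + lam * step)
      bad <- !is.finite(f_new) | f_new < f0 - 1e-12
      if (!any(bad)) break
      lam[bad] <- lam[bad] / 2
    }
    u <- u + lam * step
    f0 <- h_fun(u)
  }
  sigma <- 1 / sqrt(-h2_fun(u))
  K <- length(gh$nodes)
  acc <- matrix(NA_real_, n, K)
  pts <- matrix(NA_real_, n, K)
  for (k in seq_len(K)) {
    pts[, k] <- u + sqrt(2) * sigma * gh$nodes[k]
    acc[, k] <- log(gh$weights[k]) + gh$nodes[k]^2 + h_fun(pts[, k])
  }
  m <- apply(acc, 1, max)
  out <- log(sqrt(2) * sigma) + m + log(rowSums(exp(acc - m)))
  attr(out, "modes") <- u
  # posterior node weights and points, used for analytic score assembly
  attr(out, "points") <- pts
  attr(out, "post_w") <- exp(acc - (m + log(rowSums(exp(acc - m)))))
  out
}
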