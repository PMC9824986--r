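#' Link functions for Bernoulli regression
#'
#' Construct a link-function object for one of the three Bernoulli links
#' used throughout the package: complementary log-log (`cloglog`), `logit`
#' or `probit`.  The cloglog link, \eqn{g(p) = \log(-\log(1-p))}, is
#' asymmetric: its inverse at 0 is \eqn{1 - e^{-1} \approx 0.632}, unlike
#' the symmetric logit and probit links.
#'
#' All maps clamp probabilities to `[1e-12, 1 - 1e-12]` and linear
#' predictors to `[-30, 30]` so that log-likelihood contributions stay
#' finite for extreme fitted values.
#'
#' @param name one of `"cloglog"`, `"logit"`, `"probit"`.
#' @return An object of class `bern_link`: a list with elements `name`,
#'   `linkfun` (\eqn{g(p)\to\eta}), `linkinv` (\eqn{g^{-1}(\eta)\to p}),
#'   `mu.eta` (\eqn{dp/d\eta}) and `mu.eta2` (\eqn{d^2p/d\eta^2}, used for
#'   the observed information).
#' @examples
#' lk <- bernoulli_link("cloglog")
#' lk$linkinv(0)   # 1 - exp(-1)
#' @export
bernoulli_link <- function(name = c("cloglog", "logit", "probit")) {
  name <- match.arg(name)
  clamp_eta <- function(eta) pmin(pmax(eta, -30), 30)
  clamp_p <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)
  obj <- switch(name,
    cloglog = list(
      linkfun = function(p) log(-log1p(-clamp_p(p))),
      linkinv = function(eta) clamp_p(-expm1(-exp(clamp_eta(eta)))),
      mu.eta  = function(eta) { e <- clamp_eta(eta); exp(e - exp(e)) },
      mu.eta2 = function(eta) {
        e <- clamp_eta(eta)
        exp(e - exp(e)) * (1 - exp(e))
      }
    ),
    logit = list(
      linkfun = function(p) { p <- clamp_p(p); log(p / (1 - p)) },
      linkinv = function(eta) clamp_p(stats::plogis(clamp_eta(eta))),
      mu.eta  = function(eta) {
        p <- stats::plogis(clamp_eta(eta)); p * (1 - p)
      },
      mu.eta2 = function(eta) {
        p <- stats::plogis(clamp_eta(eta)); p * (1 - p) * (1 - 2 * p)
      }
    ),
    probit = list(
      linkfun = function(p) stats::qnorm(clamp_p(p)),
      linkinv = function(eta) clamp_p(stats::pnorm(clamp_eta(eta))),
      mu.eta  = function(eta) stats::dnorm(clamp_eta(eta)),
      mu.eta2 = function(eta) {
        e <- clamp_eta(eta); -e * stats::dnorm(e)
      }
    )
  )
  obj$name <- name
  class(obj) <- "bern_link"
  obj
}

#' @export
print.bern_link <- function(x, ...) {
  cat("<bern_link>", x$name, "\n")
  invisible(x)
}

link_names <- function() c("cloglog", "logit", "probit")

as_bern_link <- function(link) {
  if (inherits(link, "bern_link")) return(link)
  if (is.character(link) && length(link) == 1 && link %in% link_names())
    return(bernoulli_link(link))
  stop("link must be one of ", paste(link_names(), collapse = ", "),
       call. = FALSE)
}
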