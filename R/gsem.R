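#' Fit a recursive system of Bernoulli equations
#'
#' Joint maximum likelihood for the structural system defined by a
#' [path_model_spec()] with no latent factor.  Because the system is
#' recursive and the mediator (preterm birth) is fully observed, the joint
#' likelihood factorises over equations; the fitter exploits this
#' separability — each equation is maximised by [fit_bernoulli_glm()] —
#' while exposing the joint log-likelihood, joint score, stacked
#' coefficient vector and block-diagonal joint covariance that the
#' mediation machinery needs.  Coefficients are named `"outcome.term"`
#' (e.g. `"lbw.pb"`, `"pb.pm25"`).
#'
#' @param spec a `path_model_spec` without latent block (see
#'   [fit_latent_system()] otherwise).
#' @param cohort data frame containing every outcome and predictor column.
#' @param cluster optional column name for cluster-robust covariance
#'   (e.g. `"south_durban"`); stored and used by [system_sandwich()].
#' @return object of class `gsem_fit`: `fits` (per-equation `bern_glm`),
#'   `coefficients`, `vcov` (block-diagonal, model-based), `logLik`, `k`,
#'   `n`, `spec`, `link`, `cluster`.
#' @export
fit_system <- function(spec, cohort, cluster = NULL) {
  stopifnot(inherits(spec, "path_model_spec"))
  if (!is.null(spec$latent))
    stop("spec has a latent block; use fit_latent_system()", call. = FALSE)
  link <- as_bern_link(spec$link)
  missing_cols <- setdiff(
    unique(c(spec$outcomes, unlist(spec$equations))), names(cohort))
  if (length(missing_cols))
    stop("cohort lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  fits <- list()
  for (out in spec$order) {
    x <- design_matrix(cohort, spec$equations[[out]])
    fit <- tryCatch(
      fit_bernoulli_glm(x, cohort[[out]], link = link),
      error = function(e)
        stop("equation '", out, "' failed: ", conditionMessage(e),
             call. = FALSE))
    fits[[out]] <- fit
  }
  coefs <- unlist(lapply(spec$order, function(out) {
    b <- fits[[out]]$coefficients
    stats::setNames(b, paste(out, names(b), sep = "."))
  }))
  k_tot <- sum(vapply(fits, function(f) f$k, 0))
  vc <- matrix(0, k_tot, k_tot, dimnames = list(names(coefs), names(coefs)))
  pos <- 0L
  for (out in spec$order) {
    idx <- pos + seq_len(fits[[out]]$k)
    vc[idx, idx] <- fits[[out]]$vcov
    pos <- pos + fits[[out]]$k
  }
  structure(list(
    fits = fits, coefficients = coefs, vcov = vc,
    logLik = sum(vapply(fits, function(f) f$logLik, 0)),
    k = k_tot, n = nrow(cohort), spec = spec, link = link$name,
    cluster = if (!is.null(cluster)) cohort[[cluster]]
  ), class = "gsem_fit")
}

design_matrix <- function(cohort, predictors) {
  f <- stats::reformulate(predictors, intercept = TRUE)
  stats::model.matrix(f, data = cohort)
}

#' @export
coef.gsem_fit <- function(object, ...) object$coefficients

#' @export
vcov.gsem_fit <- function(object, ...) object$vcov

#' @export
logLik.gsem_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n, class = "logLik")
}

#' @export
print.gsem_fit <- function(x, ...) {
  ic <- information_criteria(x)
  cat("Generalized SEM fit (", x$link, " link): ", length(x$fits),
      " equations, n = ", x$n, "\n", sep = "")
  cat("  logLik = ", format(x$logLik, digits = 8),
      ", AIC = ", format(ic["AIC"], digits = 8),
      ", BIC = ", format(ic["BIC"], digits = 8), "\n", sep = "")
  invisible(x)
}

#' Cluster-robust joint covariance of a system fit
#'
#' Stacks per-record scores across equations, sums them within cluster and
#' sandwiches the result between the inverse block-diagonal observed
#' information, so cross-equation dependence induced by shared clusters
#' (residential location) is captured.
#'
#' @param fit a `gsem_fit`.
#' @param cluster_ids length-n cluster labels; defaults to the `cluster`
#'   stored at fit time, or per-record (HC0) if none.
#' @param correction apply the G/(G-1)*(n-1)/(n-k) finite-sample factor.
#' @return joint covariance matrix in the stacked coefficient order.
#' @export
system_sandwich <- function(fit, cluster_ids = fit$cluster,
                            correction = FALSE) {
  stopifnot(inherits(fit, "gsem_fit"))
  n <- fit$n
  s <- do.call(cbind, lapply(fit$spec$order, function(out) {
    f <- fit$fits[[out]]
    f$x * (f$weights * score_eta(f$y, f$eta, f$link))
  }))
  if (!is.null(cluster_ids)) {
    if (length(cluster_ids) != n)
      stop("cluster_ids must have length n", call. = FALSE)
    s <- rowsum(s, group = cluster_ids)
  }
  b <- crossprod(s)
  a_inv <- matrix(0, fit$k, fit$k)
  pos <- 0L
  for (out in fit$spec$order) {
    f <- fit$fits[[out]]
    idx <- pos + seq_len(f$k)
    a_inv[idx, idx] <- solve(observed_information(f$x, f$y, f$eta, f$link,
                                                  f$weights))
    pos <- pos + f$k
  }
  v <- a_inv %*% b %*% a_inv
  if (correction) {
    g <- if (is.null(cluster_ids)) n else length(unique(cluster_ids))
    v <- v * g / (g - 1) * (n - 1) / (n - fit$k)
  }
  dimnames(v) <- dimnames(fit$vcov)
  (v + t(v)) / 2
}

#' Compare Bernoulli link families by information criteria
#'
#' Fits the same system under each candidate link and tabulates AIC and
#' BIC; [select_link()] applies the selection rule (minimum AIC, ties
#' broken toward lower BIC, then lexicographically) and also works on a
#' pre-computed table of published AIC/BIC rows.
#'
#' @param spec a `path_model_spec` (its own `link` field is ignored).
#' @param cohort data frame of outcomes and predictors.
#' @param links character vector of at least two link names.
#' @return a `link_comparison`: data frame with columns `link`, `AIC`,
#'   `BIC`, `failed`, plus attribute `selected`.
#' @export
compare_links <- function(spec, cohort,
                          links = c("cloglog", "logit", "probit")) {
  links <- match.arg(links, link_names(), several.ok = TRUE)
  if (length(links) < 2) stop("need at least two links", call. = FALSE)
  rows <- lapply(links, function(lk) {
    sp <- spec; sp$link <- lk
    fit <- tryCatch(fit_system(sp, cohort), error = function(e) NULL)
    if (is.null(fit))
      data.frame(link = lk, AIC = NA_real_, BIC = NA_real_, failed = TRUE)
    else {
      ic <- information_criteria(fit)
      data.frame(link = lk, AIC = ic[["AIC"]], BIC = ic[["BIC"]],
                 failed = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  select_link(tab)
}

#' @rdname compare_links
#' @param table data frame with columns `link`, `AIC`, `BIC` (and
#'   optionally `failed`).
#' @export
select_link <- function(table) {
  stopifnot(all(c("link", "AIC", "BIC") %in% names(table)))
  if (is.null(table$failed)) table$failed <- !is.finite(table$AIC)
  ok <- table[!table$failed & is.finite(table$AIC), , drop = FALSE]
  if (nrow(ok) == 0) stop("all link fits failed", call. = FALSE)
  ord <- order(ok$AIC, ok$BIC, ok$link)
  structure(table, selected = ok$link[ord[1]],
            class = c("link_comparison", "data.frame"))
}

#' @export
print.link_comparison <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  cat("selected:", attr(x, "selected"), "\n")
  invisible(x)
}
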