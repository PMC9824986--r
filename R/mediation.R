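#' Enumerate directed paths from an exposure to an outcome
#'
#' Depth-first enumeration of every directed path from `exposure` to
#' `outcome` through the acyclic endogenous graph of a path model.  The
#' direct edge (exposure appearing in the outcome's own equation) is
#' reported separately from indirect paths, which pass through at least
#' one mediator (e.g. `pm25 -> pb -> lbw`).
#'
#' @param spec a `path_model_spec`.
#' @param exposure exogenous (or endogenous) predictor name.
#' @param outcome endogenous outcome name.
#' @return list with `direct` (character vector `c(exposure, outcome)` or
#'   `NULL` if no direct edge) and `indirect` (list of node-sequence
#'   character vectors).  No path at all gives an empty decomposition, not
#'   an error.
#' @export
enumerate_paths <- function(spec, exposure, outcome) {
  stopifnot(inherits(spec, "path_model_spec"))
  if (!outcome %in% spec$outcomes)
    stop("'", outcome, "' is not an endogenous outcome of the spec",
         call. = FALSE)
  # children of a node v: outcomes whose equation contains v
  children <- function(v)
    spec$outcomes[vapply(spec$outcomes,
                         function(o) v %in% spec$equations[[o]], TRUE)]
  paths <- list()
  walk <- function(v, trail) {
    for (w in children(v)) {
      if (w == outcome) paths[[length(paths) + 1L]] <<- c(trail, w)
      else walk(w, c(trail, w))
    }
  }
  walk(exposure, exposure)
  direct <- NULL; indirect <- list()
  for (p in paths) {
    if (length(p) == 2) direct <- p else indirect[[length(indirect) + 1L]] <- p
  }
  list(direct = direct, indirect = indirect)
}

edge_coef_name <- function(from, to) paste(to, from, sep = ".")

#' Decompose an exposure effect into direct, indirect and total parts
#'
#' Indirect effect of each path = product of its edge coefficients;
#' the summed indirect plus the direct coefficient gives the total effect.
#' All arithmetic is on the linear-predictor (link) scale — the
#' product-of-coefficients convention — and is exponentiated only for
#' display as adjusted odds ratios.  Confidence intervals use the delta
#' method on the joint covariance (model-based by default; pass a
#' clustered covariance via `vcov`).
#'
#' @param fit a `gsem_fit`.
#' @param exposure,outcome names as in [enumerate_paths()].
#' @param level confidence level.
#' @param vcov optional joint covariance matrix to use instead of the
#'   model-based one (e.g. from [system_sandwich()]).
#' @return object of class `effect_decomposition`: data frame with rows
#'   `direct`, one per indirect path, `indirect_total`, `total`; columns
#'   `effect`, `estimate`, `se`, `lower`, `upper`, `aor`, `aor_lower`,
#'   `aor_upper`, `p_value`.
#' @export
decompose_effects <- function(fit, exposure, outcome, level = 0.95,
                              vcov = NULL) {
  stopifnot(inherits(fit, "gsem_fit"))
  spec <- fit$spec
  paths <- enumerate_paths(spec, exposure, outcome)
  beta <- fit$coefficients
  vc <- if (is.null(vcov)) fit$vcov else vcov

  # coefficient of each edge; an absent edge contributes 0 with a notice
  edge_coef <- function(from, to) {
    nm <- edge_coef_name(from, to)
    if (!nm %in% names(beta)) {
      message("edge ", from, " -> ", to,
              " absent from the fitted system; treated as 0")
      return(list(value = 0, name = NA_character_))
    }
    list(value = unname(beta[nm]), name = nm)
  }

  rows <- list()
  add_row <- function(label, value, grad_names, grad_values) {
    se <- 0
    if (length(grad_names)) {
      g <- numeric(length(beta)); names(g) <- names(beta)
      g[grad_names] <- grad_values
      se <- sqrt(drop(t(g) %*% vc %*% g))
    }
    z <- stats::qnorm(1 - (1 - level) / 2)
    p <- if (se > 0) 2 * stats::pnorm(-abs(value / se)) else NA_real_
    rows[[length(rows) + 1L]] <<- data.frame(
      effect = label, estimate = value, se = se,
      lower = value - z * se, upper = value + z * se,
      aor = exp(value), aor_lower = exp(value - z * se),
      aor_upper = exp(value + z * se), p_value = p,
      stringsAsFactors = FALSE)
  }

  # direct
  if (is.null(paths$direct)) {
    add_row("direct", 0, character(0), numeric(0))
    direct_val <- 0; direct_nm <- NULL
  } else {
    ec <- edge_coef(exposure, outcome)
    direct_val <- ec$value
    direct_nm <- ec$name
    add_row("direct", direct_val,
            if (!is.na(ec$name)) ec$name else character(0), 1)
  }

  # per-path indirect products with analytic gradients
  indirect_sum <- 0
  sum_grad <- numeric(length(beta)); names(sum_grad) <- names(beta)
  for (p in paths$indirect) {
    edges <- cbind(p[-length(p)], p[-1])
    ecs <- apply(edges, 1, function(e) edge_coef(e[1], e[2]),
                 simplify = FALSE)
    vals <- vapply(ecs, function(e) e$value, 0)
    nms <- vapply(ecs, function(e) e$name, "")
    prod_val <- prod(vals)
    # d(prod)/d(coef_j) = product of the other edges
    grads <- vapply(seq_along(vals), function(j) prod(vals[-j]), 0)
    keep <- !is.na(nms)
    add_row(paste(p, collapse = " -> "), prod_val, nms[keep], grads[keep])
    indirect_sum <- indirect_sum + prod_val
    if (any(keep)) sum_grad[nms[keep]] <- sum_grad[nms[keep]] + grads[keep]
  }
  nz <- names(sum_grad)[sum_grad != 0]
  add_row("indirect_total", indirect_sum, nz, sum_grad[nz])

  total_grad <- sum_grad
  if (!is.null(direct_nm) && !is.na(direct_nm))
    total_grad[direct_nm] <- total_grad[direct_nm] + 1
  nz <- names(total_grad)[total_grad != 0]
  add_row("total", direct_val + indirect_sum, nz, total_grad[nz])

  out <- do.call(rbind, rows)
  structure(out, exposure = exposure, outcome = outcome, level = level,
            class = c("effect_decomposition", "data.frame"))
}

#' Delta-method interval for a smooth function of coefficients
#'
#' \eqn{SE = \sqrt{\nabla' V \nabla}} with the gradient evaluated at the
#' estimate: analytic if supplied, otherwise central finite differences.
#' A zero gradient collapses the interval to a point with a warning; a
#' singular covariance is an error.
#'
#' @param fit a `bern_glm` or `gsem_fit` (anything with `coefficients` and
#'   `vcov`).
#' @param expression function taking the named coefficient vector and
#'   returning a scalar.
#' @param level confidence level.
#' @param gradient optional function returning the gradient vector.
#' @param vcov optional covariance override.
#' @return list with `point`, `se`, `lower`, `upper`.
#' @export
delta_method_ci <- function(fit, expression, level = 0.95,
                            gradient = NULL, vcov = NULL) {
  beta <- fit$coefficients
  vc <- if (is.null(vcov)) fit$vcov else vcov
  if (any(!is.finite(vc))) stop("covariance unavailable", call. = FALSE)
  if (rcond(vc) < 1e-14) stop("singular covariance matrix", call. = FALSE)
  point <- expression(beta)
  g <- if (!is.null(gradient)) gradient(beta) else {
    vapply(seq_along(beta), function(j) {
      h <- 1e-6 * max(1, abs(beta[j]))
      bp <- beta; bp[j] <- bp[j] + h
      bm <- beta; bm[j] <- bm[j] - h
      (expression(bp) - expression(bm)) / (2 * h)
    }, 0)
  }
  if (all(g == 0))
    warning("zero gradient: interval collapses to a point")
  se <- sqrt(max(0, drop(t(g) %*% vc %*% g)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(point = point, se = se, lower = point - z * se, upper = point + z * se)
}

#' Bootstrap percentile interval for a function of system coefficients
#'
#' Nonparametric resampling of records (or of whole clusters when
#' `cluster_ids` is given), refitting the system on each resample and
#' taking percentile bounds of the statistic.  Replicates whose fit fails
#' (e.g. separation in a small resample) are dropped and counted; more
#' than 10% failures aborts with an instability error.
#'
#' @param spec a `path_model_spec`.
#' @param cohort data frame.
#' @param expression function of the stacked named coefficient vector.
#' @param B number of replicates (>= 200).
#' @param seed integer seed (mandatory, for reproducibility).
#' @param cluster_ids optional cluster labels for cluster resampling.
#' @param level confidence level.
#' @return list with `point` (full-data statistic), `lower`, `upper`,
#'   `se` (bootstrap SD), `B_used`, `failures`.
#' @export
bootstrap_ci <- function(spec, cohort, expression, B = 1000L, seed,
                         cluster_ids = NULL, level = 0.95) {
  if (B < 200) stop("B must be at least 200", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  full <- fit_system(spec, cohort)
  point <- expression(full$coefficients)
  rng <- new_rng(seed)
  n <- nrow(cohort)
  stats_b <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- if (is.null(cluster_ids)) {
      sample_int(rng, n, n, replace = TRUE)
    } else {
      cl <- unique(cluster_ids)
      pick <- cl[sample_int(rng, length(cl), length(cl), replace = TRUE)]
      unlist(lapply(pick, function(cc) which(cluster_ids == cc)))
    }
    fit_b <- tryCatch(fit_system(spec, cohort[idx, , drop = FALSE]),
                      error = function(e) NULL)
    if (!is.null(fit_b)) stats_b[b] <- expression(fit_b$coefficients)
  }
  failures <- sum(is.na(stats_b))
  if (failures > 0.1 * B)
    stop("bootstrap unstable: ", failures, " of ", B,
         " replicate fits failed", call. = FALSE)
  ok <- stats_b[!is.na(stats_b)]
  alpha <- (1 - level) / 2
  qs <- stats::quantile(ok, c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(point = point, lower = qs[1], upper = qs[2],
       se = stats::sd(ok), B_used = length(ok), failures = failures)
}
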