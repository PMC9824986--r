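#' Specify a recursive system of Bernoulli equations
#'
#' A path model is an ordered set of regression equations, one per
#' endogenous binary outcome, together with a common link.  Edges from one
#' endogenous variable to another (e.g. preterm birth entering the low
#' birthweight equation) form the B-matrix of the structural model; edges
#' from exogenous covariates (pollutants, clinical and socio-economic
#' factors) form the Gamma-matrix.  The endogenous graph must be acyclic:
#' the system is recursive, so \eqn{(I - B)} is trivially invertible and
#' the joint likelihood factorises over equations when the mediator is
#' observed.
#'
#' @param equations named list mapping each endogenous outcome to a one-sided
#'   formula or character vector of predictor names (e.g.
#'   `list(pb = ~ pm25 + so2, lbw = ~ pb + pm25)`).
#' @param link common link name: `"cloglog"` (default), `"logit"`, `"probit"`.
#' @param latent optional [latent_spec()] attaching one shared Gaussian
#'   factor to the equations.
#' @return object of class `path_model_spec` with elements `equations`
#'   (list of character predictor vectors), `outcomes`, `link`, `latent`,
#'   `b_edges` (endogenous -> endogenous), `g_edges` (exogenous ->
#'   endogenous) and the topological `order` of the outcomes.
#' @export
path_model_spec <- function(equations, link = "cloglog", latent = NULL) {
  if (is.null(names(equations)) || any(names(equations) == ""))
    stop("equations must be a named list (outcome = predictors)",
         call. = FALSE)
  outcomes <- names(equations)
  preds <- lapply(equations, function(eq) {
    if (inherits(eq, "formula")) all.vars(eq)
    else if (is.character(eq)) eq
    else stop("each equation must be a formula or character vector",
              call. = FALSE)
  })
  b_edges <- list(); g_edges <- list()
  for (out in outcomes) {
    endo <- intersect(preds[[out]], outcomes)
    exo <- setdiff(preds[[out]], outcomes)
    for (e in endo) b_edges[[length(b_edges) + 1L]] <- c(from = e, to = out)
    for (e in exo) g_edges[[length(g_edges) + 1L]] <- c(from = e, to = out)
  }
  order <- topological_order(outcomes, b_edges)
  spec <- structure(list(
    equations = preds, outcomes = outcomes, link = link,
    latent = latent, b_edges = b_edges, g_edges = g_edges, order = order
  ), class = "path_model_spec")
  spec
}

# Kahn's algorithm over the endogenous subgraph; names the cycle on failure
topological_order <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (e in edges) {
    adj[[e[["from"]]]] <- c(adj[[e[["from"]]]], e[["to"]])
    indeg[e[["to"]]] <- indeg[e[["to"]]] + 1L
  }
  order <- character(0)
  queue <- nodes[indeg == 0L]
  indeg_work <- indeg
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (w in adj[[v]]) {
      indeg_work[w] <- indeg_work[w] - 1L
      if (indeg_work[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(order) < length(nodes)) {
    cyc <- setdiff(nodes, order)
    stop("endogenous graph contains a cycle involving: ",
         paste(cyc, collapse = " -> "), call. = FALSE)
  }
  order
}

#' @export
print.path_model_spec <- function(x, ...) {
  cat("<path_model_spec>", length(x$outcomes), "equations,", x$link,
      "link\n")
  for (out in x$order)
    cat("  ", out, "~", paste(x$equations[[out]], collapse = " + "), "\n")
  if (!is.null(x$latent))
    cat("  latent factor on:", paste(names(x$latent$loadings),
                                     collapse = ", "), "\n")
  invisible(x)
}

#' Latent-factor block of a path model
#'
#' One shared Gaussian factor \eqn{\eta^* \sim N(0, \psi)} entering each
#' listed equation through a loading; the first loading is fixed to 1 for
#' identification.
#'
#' @param loadings named numeric vector of starting loadings (names =
#'   outcomes the factor enters); the first is held fixed.
#' @param psi starting variance of the factor (non-negative).
#' @param nodes quadrature node count (odd, default 7).
#' @return object of class `latent_spec`.
#' @export
latent_spec <- function(loadings, psi = 1, nodes = 7L) {
  stopifnot(psi >= 0, length(loadings) >= 1, !is.null(names(loadings)))
  structure(list(loadings = loadings, psi = psi, nodes = as.integer(nodes)),
            class = "latent_spec")
}

#' Default structural model for the three adverse birth outcomes
#'
#' Preterm birth (pb) is regressed on the three pollutants plus clinical,
#' behavioural, socio-economic and demographic covariates; low birthweight
#' (lbw) and small-for-gestational-age (sga) are each regressed on pb (the
#' mediator) plus their own adjusted covariate sets.  Covariates absent
#' from a given outcome's published adjustment set are excluded from that
#' equation.
#'
#' @param link link name, default `"cloglog"`.
#' @return a [path_model_spec()].
#' @export
default_model_spec <- function(link = "cloglog") {
  path_model_spec(list(
    pb = ~ pm25 + nox + so2 + weight_gain + bmi_t1 + hiv + smoker +
      alcohol + educ_primary + low_income + unemployed + female,
    lbw = ~ pb + pm25 + nox + so2 + weight_gain + bmi_t1 + syphilis +
      smoker + alcohol + educ_primary + low_income + low_se_housing +
      female,
    sga = ~ pb + pm25 + nox + so2 + weight_gain + bmi_t1 + syphilis +
      alcohol + phys_exercise + female
  ), link = link)
}

#' Serialize / deserialize a path model spec as YAML
#'
#' The on-disk form lists each equation as a formula string plus the link
#' name and any latent block; [read_model_spec()] round-trips losslessly.
#'
#' @param spec a `path_model_spec`.
#' @param path file path.
#' @return `read_model_spec` returns a `path_model_spec`.
#' @export
write_model_spec <- function(spec, path) {
  lst <- list(
    link = spec$link,
    equations = lapply(spec$equations, function(p) paste(p, collapse = " + "))
  )
  if (!is.null(spec$latent))
    lst$latent <- list(loadings = as.list(spec$latent$loadings),
                       psi = spec$latent$psi, nodes = spec$latent$nodes)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  lst <- yaml::read_yaml(path)
  eqs <- lapply(lst$equations, function(s)
    trimws(strsplit(s, "+", fixed = TRUE)[[1]]))
  latent <- NULL
  if (!is.null(lst$latent))
    latent <- latent_spec(unlist(lst$latent$loadings), lst$latent$psi,
                          lst$latent$nodes)
  path_model_spec(eqs, link = lst$link, latent = latent)
}
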