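#' Pipeline configuration
#'
#' Collects every setting of the end-to-end analysis: where the cohort
#' comes from (a [generator_config()] or a cohort CSV path), the
#' structural model, the links to compare, confidence level, bootstrap
#' replicates, multiple-imputation settings, the cluster variable for
#' robust standard errors, the root seed and the output directory.
#'
#' @param input a `generator_config` or a path to a cohort CSV.
#' @param spec a `path_model_spec`; defaults to [default_model_spec()].
#' @param links links to compare.
#' @param ci_level confidence level for all intervals.
#' @param bootstrap_B bootstrap replicates (0 disables the bootstrap).
#' @param mi_m imputations when missing cells are present.
#' @param cluster cluster column for sandwich standard errors.
#' @param seed root seed (required: the pipeline has stochastic stages).
#' @param outdir output directory (`NULL` = no files written).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, spec = default_model_spec(),
                            links = c("cloglog", "logit", "probit"),
                            ci_level = 0.95, bootstrap_B = 0L,
                            mi_m = 20L, cluster = "community",
                            seed, outdir = NULL) {
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  structure(list(input = input, spec = spec, links = links,
                 ci_level = ci_level, bootstrap_B = bootstrap_B,
                 mi_m = mi_m, cluster = cluster, seed = as.integer(seed),
                 outdir = outdir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages, in order: cohort acquisition (generate or read), eligibility
#' exclusions with a flow report, outcome derivation, multiple imputation
#' when missing cells are present, link comparison by AIC/BIC, system fit
#' under the selected link with cluster-robust covariance, and mediation
#' decompositions of each pollutant on low birthweight and
#' small-for-gestational-age.  Deterministic given the seed.  Any stage
#' failure aborts with the stage name.  When `outdir` is set, the flow
#' report, descriptive table, link comparison, coefficient table,
#' decomposition table and a JSON manifest (config hash, seed, versions,
#' record counts) are written there.
#'
#' @param config a [pipeline_config()].
#' @return a run report list: `flow`, `descriptives`, `links`,
#'   `selected_link`, `fit`, `vcov_cluster`, `decompositions`, `pooled`
#'   (if imputation ran), `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  raw <- stage("input", {
    if (inherits(config$input, "generator_config")) simulate_cohort(config$input)
    else read_cohort(config$input)
  })
  required <- unique(c("gestational_age", "birthweight",
                       unlist(config$spec$equations)))
  required <- setdiff(required, config$spec$outcomes)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("pipeline stage 'validate' failed: cohort lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  excl <- stage("exclusions", apply_exclusions(raw))
  cohort <- stage("derivation", derive_outcomes(excl$cohort))
  desc <- stage("descriptives", descriptive_table(cohort))

  has_missing <- anyNA(cohort[setdiff(required, "exclusion_flag")])
  pooled <- NULL
  fit_cohorts <- list(cohort)
  if (has_missing) {
    imps <- stage("imputation",
                  impute_chained(cohort, m = config$mi_m,
                                 seed = config$seed + 1L))
    fit_cohorts <- imps
  }

  links_tab <- stage("link_comparison",
                     compare_links(config$spec, fit_cohorts[[1]],
                                   links = config$links))
  selected <- attr(links_tab, "selected")
  spec_sel <- config$spec; spec_sel$link <- selected

  fits <- stage("system_fit", lapply(fit_cohorts, function(d)
    fit_system(spec_sel, d,
               cluster = if (config$cluster %in% names(d)) config$cluster)))
  fit <- fits[[1]]
  if (has_missing) pooled <- stage("pooling", rubin_pool(fits))
  vcc <- stage("sandwich", system_sandwich(fit))

  exposures <- intersect(c("pm25", "so2", "nox"),
                         unlist(config$spec$equations))
  outcomes <- setdiff(config$spec$outcomes, "pb")
  decomps <- list()
  for (ex in exposures) for (oc in outcomes)
    decomps[[paste(ex, oc, sep = "_")]] <- stage("mediation",
      decompose_effects(fit, ex, oc, level = config$ci_level, vcov = vcc))

  manifest <- list(
    package_version = as.character(utils::packageVersion("gsembirth")),
    seed = config$seed,
    config_hash = config_hash(list(
      spec = unclass(config$spec), links = config$links,
      ci_level = config$ci_level, mi_m = config$mi_m,
      cluster = config$cluster, seed = config$seed,
      input = if (inherits(config$input, "generator_config"))
        unclass(config$input) else config$input)),
    n_enrolled = nrow(raw),
    n_analysed = nrow(cohort),
    selected_link = selected,
    imputations = if (has_missing) config$mi_m else 0L)

  report <- list(flow = excl$flow, descriptives = desc, links = links_tab,
                 selected_link = selected, fit = fit, vcov_cluster = vcc,
                 decompositions = decomps, pooled = pooled,
                 manifest = manifest)
  if (!is.null(config$outdir)) write_pipeline_outputs(report, config)
  invisible(report)
}

write_pipeline_outputs <- function(report, config) {
  od <- config$outdir
  utils::write.csv(report$flow, file.path(od, "flow_report.csv"),
                   row.names = FALSE)
  utils::write.csv(report$descriptives,
                   file.path(od, "descriptive_table.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$links),
                   file.path(od, "link_comparison.csv"), row.names = FALSE)
  utils::write.csv(render_coefficient_table(report$fit,
                                            vcov = report$vcov_cluster,
                                            level = config$ci_level),
                   file.path(od, "coefficient_table.csv"),
                   row.names = FALSE)
  dec <- do.call(rbind, lapply(names(report$decompositions), function(nm)
    render_decomposition_table(report$decompositions[[nm]])))
  utils::write.csv(dec, file.path(od, "effect_decompositions.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(od)
}

significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

format_aor <- function(est, lo, hi, p)
  paste0(sprintf("%.1f", est), "(", sprintf("%.2f", lo), ", ",
         sprintf("%.2f", hi), ")", significance_stars(p))

#' Coefficient table on the adjusted-odds-ratio scale
#'
#' One row per coefficient with the AOR formatted `x.x(l, u)` plus
#' significance stars (`***` p<0.001, `**` p<0.01, `*` p<0.05).
#'
#' @param fit a `gsem_fit` (or `bern_glm`).
#' @param vcov optional covariance override (e.g. cluster-robust).
#' @param level confidence level.
#' @return data frame with `equation`, `term`, `estimate`, `se`, `aor`,
#'   `aor_ci`, `p_value`.
#' @export
render_coefficient_table <- function(fit, vcov = NULL, level = 0.95) {
  beta <- fit$coefficients
  vc <- if (is.null(vcov)) fit$vcov else vcov
  se <- sqrt(diag(vc))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- 2 * stats::pnorm(-abs(beta / se))
  parts <- strsplit(names(beta), ".", fixed = TRUE)
  data.frame(
    equation = vapply(parts, `[`, "", 1),
    term = vapply(parts, function(x) paste(x[-1], collapse = "."), ""),
    estimate = unname(beta), se = unname(se),
    aor = exp(unname(beta)),
    aor_ci = format_aor(exp(beta), exp(beta - z * se), exp(beta + z * se),
                        p),
    p_value = unname(p),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Indirect/total effect table
#'
#' Shapes an [decompose_effects()] result like a published
#' indirect-and-total-effects table: path label, coefficient-scale
#' estimate with CI and stars, and the exponentiated value (effect
#' ratio).
#'
#' @param decomp an `effect_decomposition`.
#' @return data frame (possibly empty apart from the header).
#' @export
render_decomposition_table <- function(decomp) {
  if (!nrow(decomp))
    return(data.frame(exposure = character(), outcome = character(),
                      path = character(), coefficient = character(),
                      effect_ratio = numeric()))
  data.frame(
    exposure = attr(decomp, "exposure"),
    outcome = attr(decomp, "outcome"),
    path = decomp$effect,
    coefficient = paste0(sprintf("%.4g", decomp$estimate),
                         " (", sprintf("%.4g", decomp$lower), ", ",
                         sprintf("%.4g", decomp$upper), ")",
                         significance_stars(decomp$p_value)),
    effect_ratio = decomp$aor,
    stringsAsFactors = FALSE, row.names = NULL)
}
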