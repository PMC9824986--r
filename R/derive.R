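#' Apply the study eligibility filters
#'
#' Removes records in the documented order — pregnancy-loss/multiplicity
#' reasons (multiple pregnancy, miscarriage, stillbirth, termination),
#' then relocation, then postdate birth (gestational age above 42 weeks;
#' exactly 42.0 is retained) — and reports each step in a flow table.
#' The postdate step removes rows flagged `postdate` or with observed
#' gestational age above 42.  Rows with missing gestational age and no
#' postdate flag are quarantined into their own flow row rather than
#' silently dropped.
#'
#' @param raw data frame with an `exclusion_flag` column (level `"none"`
#'   for eligible rows) and/or `gestational_age`.
#' @return list with `cohort` (eligible records), `flow` (data frame
#'   `filter`, `removed`, `remaining`) and `quarantined` (rows with
#'   unresolvable gestational age).
#' @export
apply_exclusions <- function(raw) {
  n0 <- nrow(raw)
  flags <- if ("exclusion_flag" %in% names(raw))
    as.character(raw$exclusion_flag) else rep("none", n0)
  keep <- rep(TRUE, n0)
  flow <- data.frame(filter = "enrolled", removed = 0L, remaining = n0,
                     stringsAsFactors = FALSE)
  step <- function(name, drop_idx) {
    drop_idx <- drop_idx & keep
    keep <<- keep & !drop_idx
    flow <<- rbind(flow, data.frame(filter = name,
                                    removed = sum(drop_idx),
                                    remaining = sum(keep)))
  }
  for (reason in c("multiple_pregnancy", "miscarriage", "stillbirth",
                   "termination"))
    step(reason, flags == reason)
  step("relocated", flags == "relocated")

  ga <- if ("gestational_age" %in% names(raw)) raw$gestational_age
  else rep(NA_real_, n0)
  quarantine <- keep & is.na(ga) & flags != "postdate"
  if (any(quarantine)) step("quarantined_missing_ga", quarantine)
  step("postdate", flags == "postdate" | (!is.na(ga) & ga > 42))

  cohort <- raw[keep, , drop = FALSE]
  rownames(cohort) <- NULL
  structure(list(cohort = cohort, flow = flow,
                 quarantined = raw[quarantine, , drop = FALSE]),
            class = "exclusion_result")
}

#' @export
print.exclusion_result <- function(x, ...) {
  print(x$flow, row.names = FALSE)
  invisible(x)
}

#' Derive the three binary outcomes from raw birth measures
#'
#' Preterm birth: gestational age below 37 completed weeks.  Low
#' birthweight: birthweight at or below 2500 g (the boundary is
#' inclusive).  Small-for-gestational-age: birthweight at or below the
#' empirical 10th percentile of birthweight among infants sharing the
#' same completed gestational week, computed within the analysis sample
#' (type-7 quantile by default; configurable because quantile conventions
#' differ).  Strata with fewer than `min_stratum` infants are pooled with
#' the nearest adjacent completed weeks until large enough, with a
#' warning.  The alternative `sga_method = "adjusted"` uses the 10th
#' percentile of residuals from a linear regression of birthweight on
#' gestational age.
#'
#' @param cohort eligible records with `gestational_age` (weeks) and
#'   `birthweight` (g).
#' @param sga_method `"stratified"` (default) or `"adjusted"`.
#' @param quantile_type passed to [stats::quantile()].
#' @param min_stratum smallest stratum size used as-is.
#' @return cohort with `pb`, `lbw`, `sga` columns (0/1).
#' @export
derive_outcomes <- function(cohort, sga_method = c("stratified", "adjusted"),
                            quantile_type = 7, min_stratum = 2L) {
  sga_method <- match.arg(sga_method)
  ga <- cohort$gestational_age
  bw <- cohort$birthweight
  if (any(is.na(ga)) || any(is.na(bw)))
    stop("gestational age / birthweight must be complete for derivation",
         call. = FALSE)
  if (any(bw <= 0)) stop("birthweight must be positive", call. = FALSE)
  if (any(ga < 20 | ga > 42))
    stop("gestational age outside 20-42 weeks; apply exclusions first",
         call. = FALSE)
  cohort$pb <- as.integer(ga < 37)
  cohort$lbw <- as.integer(bw <= 2500)
  if (sga_method == "stratified") {
    week <- floor(ga)
    weeks <- sort(unique(week))
    thr <- stats::setNames(numeric(length(weeks)), weeks)
    for (w in weeks) {
      pool <- bw[week == w]
      span <- 0
      while (length(pool) < min_stratum && span < 25) {
        span <- span + 1
        pool <- bw[abs(week - w) <= span]
        if (length(pool) >= min_stratum)
          warning("gestational-week stratum ", w, " has fewer than ",
                  min_stratum, " infants; pooled with weeks within ±",
                  span, call. = FALSE)
      }
      thr[as.character(w)] <- stats::quantile(pool, 0.1, names = FALSE,
                                              type = quantile_type)
    }
    cohort$sga <- as.integer(bw <= thr[as.character(week)])
  } else {
    res <- stats::residuals(stats::lm(bw ~ ga))
    cohort$sga <- as.integer(
      res <= stats::quantile(res, 0.1, names = FALSE, type = quantile_type))
  }
  # derived covariates from raw anthropometry when present
  if (all(c("weight_t1", "weight_t3") %in% names(cohort)))
    cohort$weight_gain <- cohort$weight_t3 - cohort$weight_t1
  if (all(c("weight_t1", "height_m") %in% names(cohort)))
    cohort$bmi_t1 <- cohort$weight_t1 / cohort$height_m^2
  cohort
}

#' Descriptive summary by outcome stratum
#'
#' For each adverse-outcome stratum (records with the outcome present):
#' medians for the pollutant exposures, percentages for binary factors and
#' mean (SD) for continuous covariates.  An empty stratum yields explicit
#' `NA`s, never zeros.
#'
#' @param cohort derived cohort.
#' @param strata outcome columns defining the strata.
#' @param variables optional named list `variable -> statistic`
#'   (`"median"`, `"percent"`, `"mean_sd"`); a default set mirrors the
#'   pollutants, behavioural, socio-economic, demographic and clinical
#'   factors.
#' @return data frame: one row per variable, one column per stratum, with
#'   a `statistic` column naming the summary.
#' @export
descriptive_table <- function(cohort, strata = c("lbw", "sga", "pb"),
                              variables = NULL) {
  if (is.null(variables))
    variables <- list(
      pm25 = "median", so2 = "median", nox = "median",
      smoker = "percent", passive_smoker = "percent", alcohol = "percent",
      educ_primary = "percent", unemployed = "percent",
      low_income = "percent", low_se_housing = "percent",
      maternal_age = "mean_sd", multiparous = "percent",
      female = "percent", hiv = "percent", syphilis = "percent",
      bmi_t1 = "mean_sd", weight_gain = "mean_sd",
      phys_exercise = "percent", south_durban = "percent")
  variables <- variables[names(variables) %in% names(cohort)]
  summarise_one <- function(v, stat, rows) {
    x <- cohort[[v]][rows]
    if (!length(x)) return(NA_character_)
    switch(stat,
           median = trimws(formatC(stats::median(x), format = "fg",
                                   digits = 3)),
           percent = sprintf("%.1f", 100 * mean(x)),
           mean_sd = sprintf("%.1f(%.1f)", mean(x), stats::sd(x)))
  }
  out <- data.frame(variable = names(variables),
                    statistic = unlist(variables),
                    stringsAsFactors = FALSE)
  for (s in strata) {
    rows <- which(cohort[[s]] == 1)
    out[[paste0(s, "_n", length(rows))]] <-
      vapply(names(variables),
             function(v) summarise_one(v, variables[[v]], rows), "")
  }
  rownames(out) <- NULL
  out
}

#' Normalised long-format data for a parallel-coordinates display
#'
#' Each requested variable is mapped to [0, 1] by min-max over the
#' analysis sample; constant columns map to 0.5 with a warning.  The
#' returned table is tidy (record, variable, value) with the outcome
#' columns carried along, and carries `mins` / `ranges` attributes so the
#' mapping can be inverted exactly.
#'
#' @param cohort derived cohort.
#' @param variables character vector of numeric/binary column names.
#' @return long data frame with attributes `mins`, `ranges`.
#' @export
prepare_parallel_coordinates <- function(cohort, variables) {
  unknown <- setdiff(variables, names(cohort))
  if (length(unknown))
    stop("unknown variable(s): ", paste(unknown, collapse = ", "),
         "; valid names: ", paste(names(cohort), collapse = ", "),
         call. = FALSE)
  n <- nrow(cohort)
  mins <- stats::setNames(numeric(length(variables)), variables)
  ranges <- mins
  norm <- matrix(NA_real_, n, length(variables),
                 dimnames = list(NULL, variables))
  for (v in variables) {
    x <- as.numeric(cohort[[v]])
    mins[v] <- min(x); ranges[v] <- max(x) - min(x)
    if (ranges[v] == 0) {
      warning("variable '", v, "' is constant; mapped to 0.5")
      norm[, v] <- 0.5
    } else norm[, v] <- (x - mins[v]) / ranges[v]
  }
  out <- data.frame(record = rep(seq_len(n), length(variables)),
                    variable = rep(variables, each = n),
                    value = as.vector(norm))
  for (oc in intersect(c("pb", "lbw", "sga"), names(cohort)))
    out[[oc]] <- rep(cohort[[oc]], length(variables))
  attr(out, "mins") <- mins
  attr(out, "ranges") <- ranges
  out
}
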