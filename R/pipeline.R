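# Full-study orchestration: covariate interpolation, the three-outcome WQS
# analyses (components, source groups, drop-component sensitivity), the
# total-mass and single-pollutant quasi-Poisson models, descriptive cohort
# summaries, and report writing.

#' Linearly interpolate covariates between anchor years
#'
#' Census-style covariates observed only at anchor years (e.g. decennial
#' census years) are filled in for every target year by straight-line
#' interpolation between consecutive anchors, per unit and variable, using
#' year as the sole predictor. Years outside the anchor span are held at the
#' nearest anchor value; anchor years pass through unchanged.
#'
#' @param anchors data frame with `unit_id`, `year`, and one column per
#'   variable, holding rows only for anchor years.
#' @param years integer vector of target years.
#' @return data frame with `unit_id`, `year` (all units x all target years)
#'   and the interpolated variables.
#' @export
interpolate_covariates <- function(anchors, years) {
  anchors <- as.data.frame(anchors)
  stopifnot(all(c("unit_id", "year") %in% names(anchors)))
  vars <- setdiff(names(anchors), c("unit_id", "year"))
  units <- unique(anchors$unit_id)
  out <- data.frame(unit_id = rep(units, each = length(years)),
                    year = rep(sort(years), times = length(units)))
  for (v in vars) out[[v]] <- NA_real_
  for (u in units) {
    a <- anchors[anchors$unit_id == u, ]
    rows <- out$unit_id == u
    for (v in vars) {
      ok <- !is.na(a[[v]])
      if (sum(ok) < 2)
        stop("single anchor year for unit ", u, ", variable ", v)
      out[[v]][rows] <- stats::approx(a$year[ok], a[[v]][ok],
                                      xout = out$year[rows],
                                      rule = 2)$y
    }
  }
  out
}

#' Classify ICD-10 underlying-cause codes into study cause groups
#'
#' Prefix-based grouping: chapters A-R are non-accidental; within them,
#' I00-I99 are cardiovascular and J00-J99 respiratory. Codes outside A-R
#' (external causes, S-Z) return `NA` and are excluded from analysis.
#'
#' @param code character vector of ICD-10 codes (e.g. `"I21.4"`).
#' @return factor with levels `cardiovascular`, `respiratory`,
#'   `other_nonaccidental`.
#' @export
icd10_cause_group <- function(code) {
  first <- toupper(substr(code, 1, 1))
  grp <- ifelse(first == "I", "cardiovascular",
         ifelse(first == "J", "respiratory",
         ifelse(first %in% LETTERS[1:18], "other_nonaccidental",
                NA_character_)))
  factor(grp, levels = c("cardiovascular", "respiratory",
                         "other_nonaccidental"))
}

#' Descriptive summary of mortality records
#'
#' Counts and percentages by cause of death, sex and race (whichever columns
#' are present), plus the mean and standard deviation of age at death.
#' Percentages are `100 * count / total` rounded to one decimal. Records may
#' be pre-aggregated: supply a count column `n` (each row then stands for
#' `n` deaths).
#'
#' @param records data frame of per-death rows (or pre-aggregated rows with
#'   a count column) with any of the columns `cause`, `sex`, `race`, `age`.
#' @param count_col optional name of the count column for pre-aggregated
#'   input.
#' @return object of class `"cohort_summary"`: a list of data frames
#'   (`n`, `pct` per category) plus `total` and `age` (mean, sd).
#' @export
summarize_cohort <- function(records, count_col = NULL) {
  records <- as.data.frame(records)
  if (!nrow(records)) stop("no mortality records to summarize")
  n_of <- if (is.null(count_col)) rep(1, nrow(records))
          else records[[count_col]]
  total <- sum(n_of)
  out <- list(total = total)
  for (v in intersect(c("cause", "sex", "race"), names(records))) {
    tab <- tapply(n_of, records[[v]], sum)
    tab <- tab[!is.na(tab)]
    out[[v]] <- data.frame(category = names(tab), n = as.vector(tab),
                           pct = round(100 * as.vector(tab) / total, 1),
                           row.names = NULL)
  }
  if ("age" %in% names(records)) {
    m <- sum(n_of * records$age) / total
    out$age <- c(mean = m,
                 sd = sqrt(sum(n_of * (records$age - m)^2) / (total - 1)))
  }
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary:", format(x$total, big.mark = ","), "deaths\n")
  for (v in intersect(c("cause", "sex", "race"), names(x))) {
    cat("\n", v, ":\n", sep = "")
    print(x[[v]], row.names = FALSE)
  }
  if (!is.null(x$age))
    cat(sprintf("\nage: mean %.2f (sd %.2f)\n", x$age["mean"], x$age["sd"]))
  invisible(x)
}

#' Study configuration for [run_full_study()]
#'
#' @param outcomes outcome count column names (default the three causes of
#'   [make_study_like_dataset()]).
#' @param q,n_bootstrap,split_fraction,seed,pooling,direction WQS settings
#'   (see [wqs()]).
#' @param group_map a [source_group_map()] for weight sums and group-mass
#'   models.
#' @param drop component labels for the drop-component sensitivity WQS
#'   (default `"K"`); `character(0)` disables it.
#' @param run_components,run_groups,run_drop,run_total_mass,run_single
#'   analysis toggles.
#' @param smooth_covariates smooth continuous confounders with penalized
#'   splines (REML) in the total-mass and single-component models; linear
#'   when `FALSE` (default, matching desk-scale problem sizes).
#' @return a `"study_config"` list.
#' @export
study_config <- function(outcomes = c("nonaccidental", "cardiovascular",
                                      "respiratory"),
                         q = 10, n_bootstrap = 250, split_fraction = 0.5,
                         seed = 1L, pooling = "mean", direction = "positive",
                         group_map = default_source_groups(),
                         drop = "K",
                         run_components = TRUE, run_groups = TRUE,
                         run_drop = TRUE, run_total_mass = TRUE,
                         run_single = TRUE,
                         smooth_covariates = FALSE) {
  if (!length(outcomes)) stop("at least one outcome label is required")
  structure(list(outcomes = outcomes, q = q, n_bootstrap = n_bootstrap,
                 split_fraction = split_fraction, seed = seed,
                 pooling = pooling, direction = direction,
                 group_map = group_map, drop = drop,
                 run_components = run_components, run_groups = run_groups,
                 run_drop = run_drop, run_total_mass = run_total_mass,
                 run_single = run_single,
                 smooth_covariates = smooth_covariates),
            class = "study_config")
}

# Quasi-Poisson RR per IQR of a single exposure column, optionally with
# penalized-spline confounders.
.single_exposure_rr <- function(data, exposure, covariate_names, population,
                                outcome, m_comparisons, smooth = FALSE) {
  y <- data[[outcome]]
  keep <- data[[population]] > 0
  y <- y[keep]
  x <- data[[exposure]][keep]
  off <- log(data[[population]][keep])
  iqr <- stats::IQR(x)
  covs <- data[keep, covariate_names, drop = FALSE]
  fit <- if (smooth && length(covariate_names)) {
    fit_quasipoisson_smooth(y, linear_X = stats::setNames(data.frame(x),
                                                          exposure),
                            smooths = as.list(covs), offset = off)
  } else {
    X <- cbind("(Intercept)" = 1,
               stats::setNames(data.frame(x), exposure),
               covs)
    fit_quasipoisson(y, as.matrix(X), offset = off)
  }
  rate_ratio(fit, exposure, scale = iqr, level = 0.95,
             m_comparisons = m_comparisons)
}

#' Run the full mixture study on an analysis dataset
#'
#' For every outcome, runs (as toggled): the components WQS model, the WQS
#' model on source-group masses, the drop-component sensitivity WQS, the
#' total-mass quasi-Poisson model (RR per interquartile-range increase), and
#' per-component quasi-Poisson models (RR per component IQR,
#' Bonferroni-adjusted over the number of components). Source-group weight
#' sums are computed from the components WQS weights. A failure in any one
#' analysis is isolated: it is recorded with its message and the remaining
#' analyses still run.
#'
#' @param data analysis data frame: components, covariates, population and
#'   outcome count columns, row per (unit, year). Rows with zero population
#'   are dropped with a message.
#' @param components component column names.
#' @param covariate_names covariate column names entering the rate models.
#' @param population population column name.
#' @param config a [study_config()].
#' @param units component units for mass aggregation (see
#'   [aggregate_group_mass()]).
#' @return object of class `"study_report"`: per-outcome results plus a run
#'   `manifest` (seeds, retention counts, config echo, package version).
#' @export
run_full_study <- function(data, components, covariate_names = character(0),
                           population = "population",
                           config = study_config(), units = NULL) {
  stopifnot(inherits(config, "study_config"))
  data <- as.data.frame(data)
  missing_cols <- setdiff(c(components, covariate_names, population,
                            config$outcomes), names(data))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  zero_pop <- data[[population]] <= 0
  if (any(zero_pop)) {
    message("dropping ", sum(zero_pop), " row(s) with nonpositive population")
    data <- data[!zero_pop, , drop = FALSE]
  }
  for (oc in config$outcomes)
    if (any(data[[oc]] < 0)) stop("negative counts in outcome ", oc)

  if (is.null(units)) units <- attr(data, "units")
  if (is.null(units)) units <- default_component_units()[components]
  fml <- stats::as.formula(paste("y ~",
                                 if (length(covariate_names))
                                   paste(covariate_names, collapse = " + ")
                                 else "1"))
  conv <- ifelse(units[components] == "ng/m3", 1e-3, 1)
  total_mass <- as.vector(as.matrix(data[components]) %*% conv)
  data$.total_mass <- total_mass

  group_panel <- tryCatch(
    aggregate_group_mass(data[c(components)], config$group_map,
                         units = units[components]),
    error = function(e) e)
  if (!inherits(group_panel, "error")) {
    group_cols <- setdiff(names(group_panel), c("unit_id", "year"))
    gdata <- cbind(data, group_panel)
  }

  try_one <- function(expr) tryCatch(expr, error = function(e)
    structure(list(message = conditionMessage(e)), class = "study_failure"))

  results <- list()
  for (oc in config$outcomes) {
    d <- data; d$y <- d[[oc]]
    res <- list()
    if (config$run_components) {
      res$components_wqs <- try_one(
        wqs(fml, d, mix = components, population = population,
            q = config$q, n_bootstrap = config$n_bootstrap,
            split_fraction = config$split_fraction,
            direction = config$direction, pooling = config$pooling,
            seed = config$seed))
      res$group_weights <- if (inherits(res$components_wqs, "wqs"))
        try_one(sum_group_weights(res$components_wqs, config$group_map))
      else res$components_wqs
    }
    if (config$run_groups) {
      res$groups_wqs <- if (inherits(group_panel, "error"))
        structure(list(message = conditionMessage(group_panel)),
                  class = "study_failure")
      else {
        gd <- gdata; gd$y <- gd[[oc]]
        try_one(wqs(fml, gd, mix = group_cols, population = population,
                    q = config$q, n_bootstrap = config$n_bootstrap,
                    split_fraction = config$split_fraction,
                    direction = config$direction, pooling = config$pooling,
                    seed = config$seed))
      }
    }
    if (config$run_drop && length(config$drop)) {
      res$drop_wqs <- try_one(
        wqs(fml, d, mix = components, population = population,
            drop = config$drop, q = config$q,
            n_bootstrap = config$n_bootstrap,
            split_fraction = config$split_fraction,
            direction = config$direction, pooling = config$pooling,
            seed = config$seed))
    }
    if (config$run_total_mass) {
      res$total_mass <- try_one(
        .single_exposure_rr(d, ".total_mass", covariate_names, population,
                            oc, m_comparisons = 1,
                            smooth = config$smooth_covariates))
    }
    if (config$run_single) {
      res$single_components <- try_one({
        rrs <- lapply(components, function(cmp)
          .single_exposure_rr(d, cmp, covariate_names, population, oc,
                              m_comparisons = length(components),
                              smooth = config$smooth_covariates))
        data.frame(component = components,
                   rr = vapply(rrs, `[[`, numeric(1), "estimate"),
                   lower = vapply(rrs, `[[`, numeric(1), "lower"),
                   upper = vapply(rrs, `[[`, numeric(1), "upper"),
                   iqr = vapply(rrs, `[[`, numeric(1), "scale"))
      })
    }
    results[[oc]] <- res
  }

  structure(list(results = results,
                 manifest = list(
                   package_version = as.character(
                     utils::packageVersion("wqsmix")),
                   seed = config$seed,
                   n_bootstrap = config$n_bootstrap,
                   outcomes = config$outcomes,
                   n_rows = nrow(data),
                   components = components,
                   covariates = covariate_names,
                   drop = config$drop,
                   retained = lapply(results, function(r)
                     if (inherits(r$components_wqs, "wqs"))
                       r$components_wqs$pooled$n_retained else NA_integer_),
                   timestamp = format(Sys.time(), tz = "UTC"))),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report:", length(x$results), "outcome(s)\n")
  for (oc in names(x$results)) {
    cat("\n==", oc, "==\n")
    r <- x$results[[oc]]
    for (nm in names(r)) {
      obj <- r[[nm]]
      if (inherits(obj, "study_failure")) {
        cat(nm, ": FAILED (", obj$message, ")\n", sep = "")
      } else if (inherits(obj, "wqs")) {
        cat(nm, ": ", sep = ""); print(obj$rate_ratio)
      } else if (inherits(obj, "rate_ratio_ci")) {
        cat(nm, ": ", sep = ""); print(obj)
      }
    }
  }
  invisible(x)
}

#' Write a study report to CSV tables and a JSON manifest
#'
#' Writes, per outcome, the pooled weight table, the rate-ratio table
#' (components/groups/drop WQS, total mass, single components) and a
#' `manifest.json` echoing seeds and configuration.
#'
#' @param report a [run_full_study()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  rr_rows <- list()
  for (oc in names(report$results)) {
    r <- report$results[[oc]]
    if (inherits(r$components_wqs, "wqs")) {
      wt <- data.frame(outcome = oc,
                       component = names(r$components_wqs$weights),
                       weight = unname(r$components_wqs$weights))
      p <- file.path(dir, paste0("weights_", oc, ".csv"))
      utils::write.csv(wt, p, row.names = FALSE)
      paths <- c(paths, p)
    }
    if (!is.null(r$group_weights) && is.data.frame(r$group_weights)) {
      p <- file.path(dir, paste0("group_weights_", oc, ".csv"))
      utils::write.csv(cbind(outcome = oc, r$group_weights), p,
                       row.names = FALSE)
      paths <- c(paths, p)
    }
    for (nm in c("components_wqs", "groups_wqs", "drop_wqs")) {
      if (inherits(r[[nm]], "wqs")) {
        rr <- r[[nm]]$rate_ratio
        rr_rows[[length(rr_rows) + 1]] <-
          data.frame(outcome = oc, analysis = nm, term = "wqs_index",
                     rr = rr$estimate, lower = rr$lower, upper = rr$upper,
                     scale = rr$scale)
      }
    }
    if (inherits(r$total_mass, "rate_ratio_ci")) {
      rr <- r$total_mass
      rr_rows[[length(rr_rows) + 1]] <-
        data.frame(outcome = oc, analysis = "total_mass",
                   term = "total_mass", rr = rr$estimate, lower = rr$lower,
                   upper = rr$upper, scale = rr$scale)
    }
    if (is.data.frame(r$single_components)) {
      p <- file.path(dir, paste0("single_components_", oc, ".csv"))
      utils::write.csv(cbind(outcome = oc, r$single_components), p,
                       row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  if (length(rr_rows)) {
    p <- file.path(dir, "rate_ratios.csv")
    utils::write.csv(do.call(rbind, rr_rows), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "manifest.json")
  jsonlite::write_json(report$manifest, p, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}

#' Read an exposure panel from CSV
#'
#' One row per (unit, year); a header row names the component columns.
#' Validates nonnegativity, uniqueness of (unit_id, year) keys, and the
#' absence of missing values.
#'
#' @param path CSV file path.
#' @param components optional component column names (default: all numeric
#'   columns except `unit_id` and `year`).
#' @export
read_exposure_panel <- function(path, components = NULL) {
  panel <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(components))
    components <- setdiff(names(panel)[vapply(panel, is.numeric, logical(1))],
                          c("unit_id", "year"))
  if (anyNA(panel[components])) stop("missing values in component columns")
  if (any(as.matrix(panel[components]) < 0))
    stop("negative concentrations in panel")
  if (all(c("unit_id", "year") %in% names(panel)) &&
      anyDuplicated(panel[c("unit_id", "year")]))
    stop("duplicate (unit_id, year) keys")
  panel
}
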