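# A priori source-group apportionment of mixture components: weights
# estimated per component are summed by emission source, and component
# masses are summed into group masses for group-level WQS models.

#' Construct a component-to-source-group map
#'
#' @param assignments data frame with columns `component`, `group`, `share`;
#'   a component may appear under several groups, with its shares summing
#'   to 1 (fractional assignment, e.g. organic carbon split 50/50 between
#'   tailpipe traffic and power-plant secondary particles).
#' @return object of class `"source_group_map"`.
#' @export
source_group_map <- function(assignments) {
  a <- as.data.frame(assignments)
  need <- c("component", "group", "share")
  if (!all(need %in% names(a)))
    stop("assignments must have columns: ", paste(need, collapse = ", "))
  if (any(a$share <= 0 | a$share > 1))
    stop("every share must be in (0, 1]")
  tot <- tapply(a$share, a$component, sum)
  bad <- names(tot)[abs(tot - 1) > 1e-12]
  if (length(bad))
    stop("shares must sum to 1 per component; offending: ",
         paste(bad, collapse = ", "))
  structure(list(assignments = a,
                 groups = unique(a$group),
                 components = unique(a$component)),
            class = "source_group_map")
}

#' Default PM2.5 source-group map (8 emission source categories)
#'
#' Eight a priori source categories for the 15 PM2.5 components: heavy fuel
#' oil combustion (V, Ni), biomass burning (K), crustal matter (Si, Ca),
#' non-tailpipe traffic (Zn, Pb, Fe, Cu), tailpipe traffic (EC, half of OC),
#' secondary particles from power plants (SO4, NO3, half of OC), secondary
#' particles from agriculture (NH4), and an unclear source (Br). Organic
#' carbon is split 50/50 between the two combustion-secondary groups.
#'
#' @return a [source_group_map()].
#' @export
default_source_groups <- function() {
  source_group_map(data.frame(
    component = c("V", "Ni", "K", "Si", "Ca", "Zn", "Pb", "Fe", "Cu",
                  "EC", "OC", "SO4", "NO3", "OC", "NH4", "Br"),
    group = c("heavy_fuel_oil", "heavy_fuel_oil", "biomass_burning",
              "crustal", "crustal",
              "non_tailpipe_traffic", "non_tailpipe_traffic",
              "non_tailpipe_traffic", "non_tailpipe_traffic",
              "tailpipe_traffic", "tailpipe_traffic",
              "power_plants_secondary", "power_plants_secondary",
              "power_plants_secondary",
              "agriculture_secondary", "unclear"),
    share = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 0.5, 1, 1, 0.5, 1, 1)))
}

#' Read a source-group map from a YAML or JSON file
#'
#' The file holds a list of records with fields `component`, `group`,
#' `share` (see [source_group_map()]).
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @export
read_source_groups <- function(path) {
  recs <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML maps")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  }
  if (!is.data.frame(recs))
    recs <- do.call(rbind, lapply(recs, as.data.frame))
  source_group_map(recs)
}

#' Sum pooled WQS weights by source group
#'
#' Each group's weight is `sum_i w_i * share(i, group)`; a single-component
#' group's weight equals that component's weight exactly, and the group
#' weights conserve the total (sum to 1 for simplex weights).
#'
#' @param weights a fitted [wqs()] model, a [pool_weights()] result, or a
#'   named weight vector.
#' @param map a [source_group_map()]; defaults to [default_source_groups()].
#' @return data frame with `group`, `weight` and a `components` provenance
#'   column, sorted by descending weight.
#' @export
sum_group_weights <- function(weights, map = default_source_groups()) {
  w <- if (inherits(weights, "wqs")) weights$weights
       else if (inherits(weights, "wqs_weights")) weights$w
       else weights
  if (is.null(names(w))) stop("weights must be named by component")
  stopifnot(inherits(map, "source_group_map"))
  uncovered <- setdiff(names(w), map$components)
  if (length(uncovered))
    stop("source-group map does not cover component(s): ",
         paste(uncovered, collapse = ", "))
  a <- map$assignments[map$assignments$component %in% names(w), ]
  gw <- vapply(map$groups, function(g) {
    rows <- a[a$group == g, ]
    sum(w[rows$component] * rows$share)
  }, numeric(1))
  prov <- vapply(map$groups, function(g) {
    rows <- a[a$group == g, ]
    paste(ifelse(rows$share < 1,
                 sprintf("%s x %.2g", rows$component, rows$share),
                 rows$component), collapse = ", ")
  }, character(1))
  out <- data.frame(group = map$groups, weight = unname(gw),
                    components = unname(prov), row.names = NULL)
  out[order(-out$weight), ]
}

#' Default measurement units for the 15 PM2.5 components
#'
#' Major components (sulfate, nitrate, ammonium, organic and elemental
#' carbon) are reported in micrograms per cubic metre; the ten trace
#' elements in nanograms per cubic metre.
#'
#' @return named character vector of units (`"ug/m3"` or `"ng/m3"`).
#' @export
default_component_units <- function() {
  c(SO4 = "ug/m3", NO3 = "ug/m3", NH4 = "ug/m3", OC = "ug/m3", EC = "ug/m3",
    Zn = "ng/m3", V = "ng/m3", K = "ng/m3", Si = "ng/m3", Pb = "ng/m3",
    Ni = "ng/m3", Fe = "ng/m3", Cu = "ng/m3", Ca = "ng/m3", Br = "ng/m3")
}

#' Aggregate component concentrations into source-group masses
#'
#' Converts every component to a common mass unit (micrograms per cubic
#' metre) and sums `share(i, group) * conc_i` per row and group. The result
#' is a valid exposure panel whose "components" are the source groups, so it
#' can be fed directly to [wqs()] for the group-level mixture model. Total
#' mass is conserved: summing the group masses recovers the summed
#' (converted) component masses.
#'
#' @param panel exposure panel data frame (with optional `unit_id`/`year`
#'   key columns carried through).
#' @param map a [source_group_map()].
#' @param units named character vector giving each component's unit,
#'   `"ug/m3"` or `"ng/m3"`; defaults to [default_component_units()] entries
#'   for the panel's components, or the panel's `"units"` attribute.
#' @return data frame of group masses in micrograms per cubic metre, with
#'   attribute `units`.
#' @export
aggregate_group_mass <- function(panel, map = default_source_groups(),
                                 units = NULL) {
  stopifnot(inherits(map, "source_group_map"))
  panel <- as.data.frame(panel)
  comps <- intersect(map$components, names(panel))
  uncovered <- setdiff(
    setdiff(names(panel)[vapply(panel, is.numeric, logical(1))],
            c("unit_id", "year")),
    map$components)
  if (length(uncovered))
    stop("source-group map does not cover component(s): ",
         paste(uncovered, collapse = ", "))
  if (is.null(units)) units <- attr(panel, "units")
  if (is.null(units)) units <- default_component_units()[comps]
  bad_unit <- setdiff(units[comps], c("ug/m3", "ng/m3"))
  if (length(bad_unit) || anyNA(units[comps]))
    stop("unknown unit(s): ", paste(unique(bad_unit), collapse = ", "))
  conv <- ifelse(units[comps] == "ng/m3", 1e-3, 1)
  names(conv) <- comps
  out <- panel[intersect(c("unit_id", "year"), names(panel))]
  for (g in map$groups) {
    rows <- map$assignments[map$assignments$group == g &
                              map$assignments$component %in% comps, ]
    if (!nrow(rows)) next
    m <- rep(0, nrow(panel))
    for (i in seq_len(nrow(rows))) {
      cmp <- rows$component[i]
      m <- m + rows$share[i] * conv[[cmp]] * panel[[cmp]]
    }
    out[[g]] <- m
  }
  attr(out, "units") <- stats::setNames(
    rep("ug/m3", length(setdiff(names(out), c("unit_id", "year")))),
    setdiff(names(out), c("unit_id", "year")))
  out
}
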