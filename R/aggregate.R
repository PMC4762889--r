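CLIMATE_VARS <- c("mat", "t_min", "t_max", "precip")

#' Validate a plot table
#'
#' Checks the schema shared by the generator and the pipeline: plot
#' identity, district and region membership, representation area (ha),
#' dominant species, stand age, site productivity class, organic-layer
#' thickness (m), first inventory year and back-cast rule class.
#'
#' @param plots A `data.frame` of plots.
#' @return The table, invisibly; errors describe what is missing.
#' @export
validate_plots <- function(plots) {
  need <- c("plot_id", "district", "region", "rep_area_ha", "species",
            "age", "site_class", "org_layer_m", "first_year", "rule_class")
  miss <- setdiff(need, names(plots))
  if (length(miss)) stop("plot table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyNA(plots$district)) stop("plot(s) without district: ",
                                  paste(plots$plot_id[is.na(plots$district)],
                                        collapse = ", "))
  if (any(plots$rep_area_ha <= 0)) stop("representation areas must be > 0")
  if (anyDuplicated(plots$plot_id)) stop("duplicate plot ids")
  invisible(plots)
}

#' Inventory years of a plot
#'
#' The 5-year re-measurement cycle: first inventory year, then every 5th
#' year up to `last_year`.
#'
#' @param first_year First inventory year.
#' @param last_year Last simulation year.
#' @return Integer vector of inventory years.
#' @export
inventory_years <- function(first_year, last_year) {
  seq.int(first_year, last_year, by = 5L)
}

#' Aggregate climate input across spatial and temporal scales
#'
#' Produces the per-plot, per-year climate actually fed to the model under
#' one aggregation scheme.  Spatially, each plot either keeps its own
#' climate (`"plot"`), or receives the unweighted mean over all plots of its
#' district (`"district"`) or of the whole country (`"country"`), computed
#' per variable and per year.  Temporally, each plot-year either receives
#' the fixed mean over the reference period (`"longterm"`, default
#' 1991-2008) for every simulation year, the mean of the years of its own
#' 5-year inventory interval (`"fiveyear"`, windows anchored at the plot's
#' first inventory year and extended backward over the historical period),
#' or the year's own record (`"annual"`).
#'
#' @param plots Plot table ([validate_plots()]).
#' @param climate Climate table: columns `plot_id`, `year`, `mat`, `t_min`,
#'   `t_max`, `precip`, covering every plot and every year of `years`.
#' @param spatial `"plot"`, `"district"` or `"country"`.
#' @param temporal `"longterm"`, `"fiveyear"` or `"annual"`.
#' @param years Simulation years the output must cover (default: all years
#'   present in `climate`).
#' @param longterm_years Reference years for the long-term mean.
#' @return A `data.frame` with columns `plot_id`, `year` and the four
#'   climate variables: exactly one record per plot-year.
#' @export
aggregate_climate <- function(plots, climate, spatial = "plot",
                              temporal = "longterm",
                              years = sort(unique(climate$year)),
                              longterm_years = 1991:2008) {
  spatial <- match.arg(spatial, c("plot", "district", "country"))
  temporal <- match.arg(temporal, c("longterm", "fiveyear", "annual"))
  validate_plots(plots)
  validate_climate(climate)
  cl <- climate[climate$plot_id %in% plots$plot_id, , drop = FALSE]

  have <- split(cl$year, cl$plot_id)
  need_years <- if (temporal == "longterm") {
    sort(unique(c(years, longterm_years)))
  } else years
  gaps <- lapply(have, function(y) setdiff(need_years, y))
  bad <- names(gaps)[lengths(gaps) > 0]
  if (length(bad))
    stop("climate series missing years for plot(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         ": ", paste(utils::head(sort(unique(unlist(gaps))), 10),
                     collapse = ", "))
  missing_plots <- setdiff(plots$plot_id, cl$plot_id)
  if (length(missing_plots))
    stop("no climate series for plot(s): ",
         paste(utils::head(missing_plots, 5), collapse = ", "))

  # spatial aggregation: unweighted mean over member plots, per year
  if (spatial != "plot") {
    grp <- if (spatial == "district") {
      plots$district[match(cl$plot_id, plots$plot_id)]
    } else rep(1L, nrow(cl))
    key <- interaction(cl$year, grp, drop = TRUE)
    for (v in CLIMATE_VARS) cl[[v]] <- stats::ave(cl[[v]], key, FUN = mean)
  }

  # temporal aggregation
  if (temporal == "longterm") {
    ref <- cl[cl$year %in% longterm_years, , drop = FALSE]
    agg <- stats::aggregate(ref[CLIMATE_VARS], by = list(plot_id = ref$plot_id),
                            FUN = mean)
    out <- expand.grid(plot_id = plots$plot_id, year = years,
                       KEEP.OUT.ATTRS = FALSE)
    out <- cbind(out, agg[match(out$plot_id, agg$plot_id), CLIMATE_VARS])
  } else if (temporal == "fiveyear") {
    cl <- cl[cl$year %in% years, , drop = FALSE]
    fy <- plots$first_year[match(cl$plot_id, plots$plot_id)]
    win <- floor((cl$year - fy) / 5)
    key <- interaction(cl$plot_id, win, drop = TRUE)
    for (v in CLIMATE_VARS) cl[[v]] <- stats::ave(cl[[v]], key, FUN = mean)
    out <- cl[c("plot_id", "year", CLIMATE_VARS)]
  } else {
    out <- cl[cl$year %in% years, c("plot_id", "year", CLIMATE_VARS)]
  }
  rownames(out) <- NULL
  out[order(out$plot_id, out$year), , drop = FALSE]
}

#' Climate-dependence-factor diagnostics
#'
#' Computes the dimensionless climate dependence factor for every plot-year
#' of an aggregated climate assignment and summarizes it overall, by region
#' and by 5-year period (medians, means, range) — the diagnostics used to
#' understand how aggregation changes the effective decomposition forcing.
#'
#' @param plots Plot table.
#' @param climate_agg Output of [aggregate_climate()].
#' @param params An `awenh_params` set.
#' @param use_sinusoid Passed to [climate_modifier()].
#' @return A list: `factors` (per plot-year data.frame with `region`),
#'   `overall` (median, mean, min, max over plots, computed on each plot's
#'   time-mean factor), `by_region` (the same per region) and `by_period`
#'   (median factor per region x 5-year calendar period).
#' @export
dependence_factor_summary <- function(plots, climate_agg,
                                      params = yasso07_params(),
                                      use_sinusoid = FALSE) {
  f <- climate_modifier(climate_agg$mat, climate_agg$precip, params,
                        climate_agg$t_min, climate_agg$t_max,
                        use_sinusoid = use_sinusoid)
  fac <- data.frame(plot_id = climate_agg$plot_id, year = climate_agg$year,
                    factor = f,
                    region = plots$region[match(climate_agg$plot_id,
                                                plots$plot_id)])
  per_plot <- stats::aggregate(factor ~ plot_id + region, data = fac,
                               FUN = mean)
  overall <- c(median = stats::median(per_plot$factor),
               mean = mean(per_plot$factor),
               min = min(per_plot$factor), max = max(per_plot$factor))
  by_region <- do.call(rbind, lapply(split(per_plot, per_plot$region),
    function(d) data.frame(region = d$region[1],
                           median = stats::median(d$factor),
                           mean = mean(d$factor),
                           min = min(d$factor), max = max(d$factor))))
  rownames(by_region) <- NULL
  fac$period <- 5L * (fac$year %/% 5L)
  by_period <- stats::aggregate(factor ~ region + period, data = fac,
                                FUN = stats::median)
  names(by_period)[names(by_period) == "factor"] <- "median_factor"
  list(factors = fac, overall = overall, by_region = by_region,
       by_period = by_period)
}
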