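#' Steady-state spin-up of the soil pools
#'
#' Initializes the five chemical pools by running the model for a long
#' stretch of years (default 5000 annual steps) under constant climate and
#' constant litter input, one run per woody size class.  The result is
#' checked against the analytic [steady_state()]; if the final relative
#' change per step still exceeds `tol`, a warning reports the residual so
#' non-converging configurations are visible rather than silent.
#'
#' @param params An `awenh_params` set.
#' @param normal_climate A single-row climate record (typically the 30-year
#'   climate normal used for initialization), or a plain numeric climate
#'   factor.
#' @param litter_input Constant annual litter input: a size-class x pool
#'   matrix from [cohorts_to_input()], or a list of `litter_cohort`s.
#' @param years Number of annual steps (default 5000).
#' @param size_classes Woody size classes (cm) matching the input rows.
#' @param tol Convergence tolerance on the relative change of total stock
#'   over the final step.
#' @param use_sinusoid Passed to [climate_modifier()].
#' @return A size-class x pool matrix of steady pools (kg C m^-2), with
#'   attribute `converged` (logical) and `analytic` (the [steady_state()]
#'   solution for comparison).
#' @export
spin_up <- function(params, normal_climate, litter_input, years = 5000,
                    size_classes = c(0, 2, 10), tol = 1e-6,
                    use_sinusoid = FALSE) {
  cf <- if (is.numeric(normal_climate) && is.null(dim(normal_climate))) {
    normal_climate
  } else {
    climate_modifier(normal_climate$mat, normal_climate$precip, params,
                     normal_climate$t_min, normal_climate$t_max,
                     use_sinusoid = use_sinusoid)
  }
  if (length(cf) != 1L || !is.finite(cf) || cf < 0)
    stop("spin-up needs a single non-negative climate factor")
  if (is.list(litter_input) && !is.matrix(litter_input))
    litter_input <- cohorts_to_input(litter_input, size_classes)
  if (!is.matrix(litter_input) || nrow(litter_input) != length(size_classes))
    stop("litter_input must have one row per size class")

  out <- matrix(0, length(size_classes), 5,
                dimnames = list(paste0("d", size_classes), POOLS))
  analytic <- out
  converged <- TRUE
  for (i in seq_along(size_classes)) {
    sf <- size_modifier(size_classes[i], params)
    b <- as.numeric(litter_input[i, ])
    if (all(b == 0) && cf > 0) { next }  # zero input decays to zero pools
    prop <- pool_propagator(params, sf)
    x <- rep(0, 5)
    last <- x
    xm <- matrix(x, 1); bm <- matrix(b, 1)
    for (t in seq_len(years)) {
      last <- xm
      xm <- propagate_pools(xm, bm, prop, cf)
    }
    out[i, ] <- xm[1, ]
    rel <- abs(sum(xm) - sum(last)) / max(sum(xm), .Machine$double.eps)
    if (rel > tol) converged <- FALSE
    if (cf > 0) analytic[i, ] <- steady_state(params, cf, sf, b)
  }
  if (!converged)
    warning("spin-up not converged to tol = ", tol,
            " after ", years, " steps; pools may not be at steady state")
  attr(out, "converged") <- converged
  attr(out, "analytic") <- analytic
  out
}

#' Rule parameters for historical litter back-casting
#'
#' Loads the structured configuration controlling [back_cast_litter()]:
#' the per-cycle biomass change rate used to back-project mature stands,
#' the biomass scale assumed before a land-use change, and lookup tables of
#' recommended harvest age and stand biomass at harvest age by species and
#' site productivity class.
#'
#' @param file Optional path to an alternative YAML file with the same keys.
#' @return A named list.
#' @export
backcast_rules <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "backcast_rules.yaml", package = "awenh",
                        mustWork = TRUE)
  rules <- yaml::read_yaml(file)
  need <- c("mature_change_rate", "prior_litter_scale", "harvest_age",
            "mature_biomass")
  miss <- setdiff(need, names(rules))
  if (length(miss)) stop("rules config missing key(s): ",
                         paste(miss, collapse = ", "))
  rules
}

#' Historical biomass series for the pre-simulation period
#'
#' Reconstructs, deterministically from the plot's first-inventory
#' attributes alone, how stand biomass developed before the first inventory
#' so a historical litter series can be fed to the model between the
#' steady-state spin-up and the observed inventory series.  One of five rule
#' classes applies per plot (`plot$rule_class`):
#'
#' * `"mature"` — stands older than 34 years: biomass is back-projected by
#'   the mean per-cycle change rate, `biomass[t-5] = biomass[t] / (1 + r)`,
#'   stepwise per 5-year cycle.
#' * `"young_unproductive"` — biomass held constant at the first-inventory
#'   level.
#' * `"young_productive"` — continuous forest cover: the current young stand
#'   is traced back to age zero (linear in age, stepwise per cycle); before
#'   its establishment the previous rotation stands at the configured
#'   biomass for its recommended harvest age, and its harvest at the
#'   current stand's establishment year releases a residue pulse spread
#'   over that 5-year cycle.
#' * `"land_use_change"` — before the current forest, litter input is set by
#'   a configured prior biomass scale.
#' * `"northern_constant"` — low-productivity plots: stand development
#'   traced back to age zero, zero tree biomass (ground vegetation only)
#'   further back.
#'
#' Ground vegetation is held constant throughout the historical period.
#'
#' @param plot A one-row data.frame (or list) with `species`, `age`,
#'   `site_class` (`"low"`, `"medium"`, `"high"`), `rule_class` and
#'   `first_year` (first inventory year).
#' @param biomass_first_total Total tree biomass at first inventory, kg C
#'   m^-2 (used to express the previous rotation's absolute biomass as a
#'   scale of the current stand's).
#' @param rules Configuration from [backcast_rules()].
#' @param start_year First historical year (default 1956).
#' @return A `data.frame` with one row per year `start_year` to
#'   `first_year - 1`: `year`, `tree_scale` (multiplier on first-inventory
#'   tree components), `prev_scale` (multiplier representing the previous
#'   rotation's standing biomass) and `harvest_frac` (annual fraction of the
#'   previous rotation's biomass released as harvest residue).
#' @export
back_cast_litter <- function(plot, biomass_first_total,
                             rules = backcast_rules(), start_year = 1956) {
  plot <- as.list(plot)
  for (f in c("species", "age", "site_class", "rule_class", "first_year"))
    if (is.null(plot[[f]])) stop("plot missing attribute: ", f)
  years <- seq.int(start_year, plot$first_year - 1L)
  n <- length(years)
  if (n < 1L) stop("start_year must precede the first inventory year")
  out <- data.frame(year = years, tree_scale = 1, prev_scale = 0,
                    harvest_frac = 0)
  # completed 5-year cycles between each year and the first inventory
  cycles_back <- ceiling((plot$first_year - years) / 5)
  age_at <- plot$age - (plot$first_year - years)   # stand age in year y

  rc <- plot$rule_class
  if (rc == "mature") {
    r <- rules$mature_change_rate
    out$tree_scale <- (1 + r)^(-cycles_back)
  } else if (rc == "young_unproductive") {
    out$tree_scale <- 1
  } else if (rc == "northern_constant") {
    out$tree_scale <- pmax(0, age_at) / max(plot$age, 1)
  } else if (rc == "land_use_change") {
    born <- plot$first_year - plot$age
    out$tree_scale <- ifelse(years >= born,
                             pmax(0, age_at) / max(plot$age, 1),
                             rules$prior_litter_scale)
  } else if (rc == "young_productive") {
    born <- plot$first_year - plot$age
    out$tree_scale <- ifelse(years >= born,
                             pmax(0, age_at) / max(plot$age, 1), 0)
    mature_b <- rules$mature_biomass[[plot$species]][[plot$site_class]]
    if (is.null(mature_b))
      stop("no mature-biomass entry for ", plot$species, "/",
           plot$site_class)
    prev_scale <- mature_b / max(biomass_first_total, .Machine$double.eps)
    out$prev_scale <- ifelse(years < born, prev_scale, 0)
    # harvest of the previous rotation: residue pulse spread over the
    # 5-year cycle starting at the establishment year
    pulse <- years >= born & years < born + 5
    out$harvest_frac[pulse] <- prev_scale / 5
  } else {
    stop("unclassifiable plot: unknown rule_class '", rc, "' (plot ",
         if (!is.null(plot$plot_id)) plot$plot_id else "?", "); rule trace: ",
         "age=", plot$age, " site=", plot$site_class)
  }
  # stepwise-constant litter within 5-year periods
  if (rc %in% c("northern_constant", "land_use_change", "young_productive")) {
    step_of <- ave(out$tree_scale, cycles_back, FUN = function(v) v[length(v)])
    out$tree_scale <- step_of
  }
  out
}
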