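#' The five named simulations
#'
#' The factorial design crosses spatial aggregation of climate input (plot,
#' district, country) with temporal aggregation (long-term mean, 5-year
#' mean, annual): simulation I (plot x long-term, the reporting standard),
#' II (district x long-term), III (country x long-term), IV (plot x
#' 5-year) and V (plot x annual).  Litter input is never aggregated — only
#' the climate assignment differs between simulations.
#'
#' @param sim `"I"` to `"V"`, or `NULL` to build an explicitly flagged
#'   extension from `spatial`/`temporal`.
#' @param spatial,temporal Scheme selectors (`plot|district|country`,
#'   `longterm|fiveyear|annual`) for extensions.
#' @return A list of class `awenh_config` with `name`, `spatial`,
#'   `temporal`.
#' @export
simulation_config <- function(sim = NULL, spatial = NULL, temporal = NULL) {
  designs <- list(I = c("plot", "longterm"), II = c("district", "longterm"),
                  III = c("country", "longterm"), IV = c("plot", "fiveyear"),
                  V = c("plot", "annual"))
  if (!is.null(sim)) {
    sim <- match.arg(sim, names(designs))
    spatial <- designs[[sim]][1]; temporal <- designs[[sim]][2]
    name <- sim
  } else {
    spatial <- match.arg(spatial, c("plot", "district", "country"))
    temporal <- match.arg(temporal, c("longterm", "fiveyear", "annual"))
    hit <- vapply(designs, function(d) all(d == c(spatial, temporal)),
                  logical(1))
    name <- if (any(hit)) names(designs)[hit] else
      paste0("extension:", spatial, "-", temporal)
  }
  structure(list(name = name, spatial = spatial, temporal = temporal),
            class = "awenh_config")
}

#' Keep only upland (mineral-soil) plots
#'
#' The model's domain is upland forest: plots whose organic soil horizon is
#' strictly thinner than 0.4 m.  Plots at or above the threshold are
#' dropped.
#'
#' @param plots Plot table with column `org_layer_m`.
#' @param threshold_m Thickness threshold, m (default 0.4).
#' @return The filtered plot table.
#' @export
filter_upland <- function(plots, threshold_m = 0.4) {
  if (is.null(plots$org_layer_m)) stop("plots lack org_layer_m")
  plots[plots$org_layer_m < threshold_m, , drop = FALSE]
}

# per-species litter basis: annual litter input matrices (size class x pool)
# per unit biomass of each component, built through the public cohort
# functions so the fast path and the bookkeeping path cannot diverge
litter_basis <- function(turnover = default_turnover(),
                         awen_table = default_awen(),
                         size_classes = c(0, 2, 10)) {
  tree_comps <- names(TREE_COMPONENTS)
  gv_comps <- paste0("gv_", GV_CLASSES)
  comps <- c(tree_comps, gv_comps)
  basis <- list()
  for (sp in c("spruce", "pine", "deciduous")) {
    living <- mort <- harv <- matrix(
      0, length(comps), length(size_classes) * 5,
      dimnames = list(comps, NULL))
    for (cmp in comps) {
      unit <- setNames(list(1), cmp)
      living[cmp, ] <- as.vector(cohorts_to_input(
        litter_from_living(unit, sp, turnover, awen_table), size_classes))
      if (cmp %in% tree_comps) {
        mort[cmp, ] <- as.vector(cohorts_to_input(
          litter_from_mortality_and_harvest(unit, sp, mortality_fraction = 1,
                                            awen_table = awen_table),
          size_classes))
        harv[cmp, ] <- as.vector(cohorts_to_input(
          litter_from_mortality_and_harvest(unit, sp, harvest_fraction = 1,
                                            awen_table = awen_table),
          size_classes))
      }
    }
    basis[[sp]] <- list(living = living, mort = mort, harv = harv)
  }
  attr(basis, "size_classes") <- size_classes
  attr(basis, "comps") <- comps
  basis
}

#' Build the full annual litter-input series for a landscape
#'
#' Converts per-cycle biomass into the annual, chemically partitioned,
#' size-classed litter input driving the model: for each plot, living-tree
#' and ground-vegetation turnover litter plus natural-mortality litter plus
#' harvest residues (constant within each 5-year inventory cycle; harvest
#' residue spread evenly over the cycle of the harvest), preceded by the
#' historical series from [back_cast_litter()] and topped by the
#' steady-state spin-up input: group-mean litter by dominant species and
#' site productivity class at first inventory.
#'
#' @param plots Plot table.
#' @param biomass Biomass table ([validate_biomass()]).
#' @param turnover,awen_table Turnover and chemistry tables.
#' @param rules Back-cast rules.
#' @param years Simulation years (default 1956:2012).
#' @param size_classes Woody size classes, cm.
#' @return A list of class `awenh_litter`: `input` (array plot x year x
#'   size class x pool, kg C m^-2 yr^-1), `spin_input` (plot x size class x
#'   pool), `years`, `size_classes`.
#' @export
build_litter_series <- function(plots, biomass,
                                turnover = default_turnover(),
                                awen_table = default_awen(),
                                rules = backcast_rules(),
                                years = 1956:2012,
                                size_classes = c(0, 2, 10)) {
  validate_plots(plots)
  validate_biomass(biomass)
  basis <- litter_basis(turnover, awen_table, size_classes)
  comps <- attr(basis, "comps")
  tree_comps <- names(TREE_COMPONENTS)
  n <- nrow(plots); ny <- length(years); nd <- length(size_classes)
  input <- array(0, c(n, ny, nd, 5),
                 dimnames = list(plots$plot_id, years,
                                 paste0("d", size_classes), POOLS))
  spin <- array(0, c(n, nd, 5))
  first_living <- matrix(0, n, nd * 5)

  bm_by_plot <- split(biomass, biomass$plot_id)
  for (i in seq_len(n)) {
    p <- plots[i, ]
    bb <- bm_by_plot[[as.character(p$plot_id)]]
    if (is.null(bb)) stop("missing litter/biomass series for plot ",
                          p$plot_id)
    bb <- bb[order(bb$year), , drop = FALSE]
    bs <- basis[[p$species]]
    vec <- function(row, which_comps = comps) {
      v <- setNames(numeric(length(comps)), comps)
      v[which_comps] <- as.numeric(row[which_comps])
      v
    }
    # current series: one composition per inventory cycle
    for (j in seq_len(nrow(bb))) {
      v <- vec(bb[j, ])
      ann <- v %*% bs$living +
        bb$mortality_frac[j] * (v %*% bs$mort) +
        (bb$harvest_frac[j] / 5) * (v %*% bs$harv)
      cyc <- bb$year[j]:min(bb$year[j] + 4L, max(years))
      cyc <- cyc[cyc %in% years]
      for (y in cyc) input[i, match(y, years), , ] <- ann
      if (j == 1L) first_living[i, ] <- v %*% bs$living
    }
    last_cycle_end <- max(bb$year) + 4L
    if (last_cycle_end < max(years))
      stop("missing litter years for plot ", p$plot_id, ": ",
           last_cycle_end + 1L, "-", max(years))
    # historical series from the back-cast rules
    if (min(years) < p$first_year) {
      b1 <- bb[1, ]
      tree_total <- sum(as.numeric(b1[tree_comps]))
      bc <- back_cast_litter(p, tree_total, rules, start_year = min(years))
      v_tree <- vec(b1, tree_comps)        # tree components only
      v_gv <- vec(b1, paste0("gv_", GV_CLASSES))
      gv_ann <- v_gv %*% bs$living
      tree_live <- v_tree %*% bs$living
      tree_mort <- v_tree %*% bs$mort
      tree_harv <- v_tree %*% bs$harv
      mf <- b1$mortality_frac
      for (r in seq_len(nrow(bc))) {
        y <- bc$year[r]
        if (!y %in% years) next
        sc <- bc$tree_scale[r] + bc$prev_scale[r]
        ann <- sc * tree_live + gv_ann + mf * sc * tree_mort +
          bc$harvest_frac[r] * tree_harv
        input[i, match(y, years), , ] <- ann
      }
    }
  }

  # spin-up input: group-mean first-inventory living litter by
  # species x site productivity class
  grp <- interaction(plots$species, plots$site_class, drop = TRUE)
  for (g in levels(grp)) {
    idx <- which(grp == g)
    gm <- colMeans(first_living[idx, , drop = FALSE])
    for (i in idx) spin[i, , ] <- matrix(gm, nd, 5)
  }
  structure(list(input = input, spin_input = spin, years = years,
                 size_classes = size_classes), class = "awenh_litter")
}

#' Run one aggregation simulation end-to-end
#'
#' For every plot: compute the 1961-1990 climate normal from the plot's own
#' series, initialize the pools at the analytic steady state under the
#' normal climate and the group-mean spin-up litter (equivalent to the
#' 5000-step spin-up within numerical tolerance), then advance the model
#' annually with the litter series and the climate assignment of the chosen
#' aggregation scheme.  Deterministic given its inputs.
#'
#' @param config An `awenh_config` from [simulation_config()], or a
#'   simulation name `"I"`..`"V"`.
#' @param plots Plot table (typically [filter_upland()]ed).
#' @param climate Plot-level climate table covering 1961 to the last
#'   simulation year.
#' @param litter An `awenh_litter` from [build_litter_series()] (build once
#'   and reuse across simulations — litter is never aggregated).
#' @param params An `awenh_params` set.
#' @param years Simulation years (default the litter series years).
#' @param normal_years Years of the spin-up climate normal (default
#'   1961:1990).
#' @param use_sinusoid Passed to [climate_modifier()].
#' @return An object of class `awenh_sim`: `stocks` (plot x year matrix of
#'   total soil carbon, kg C m^-2, recorded at the end of each year),
#'   `initial` (steady-state total at the start), `pools` (final plot x
#'   size class x pool array), `config`, `years`, `plots`.
#' @export
run_simulation <- function(config, plots, climate, litter,
                           params = yasso07_params(),
                           years = litter$years, normal_years = 1961:1990,
                           use_sinusoid = FALSE) {
  if (is.character(config)) config <- simulation_config(config)
  stopifnot(inherits(config, "awenh_config"),
            inherits(litter, "awenh_litter"))
  validate_plots(plots)
  if (!identical(as.integer(years), as.integer(litter$years)))
    stop("litter series years do not match the simulation years")
  n <- nrow(plots); ny <- length(years)
  sz <- litter$size_classes; nd <- length(sz)
  if (dim(litter$input)[1] != n)
    stop("litter series was built for a different plot set")

  # spin-up normal: per-plot mean climate 1961-1990, then the factor
  norm <- climate[climate$plot_id %in% plots$plot_id &
                    climate$year %in% normal_years, , drop = FALSE]
  if (!nrow(norm)) stop("climate series does not cover the normal period")
  nag <- stats::aggregate(norm[CLIMATE_VARS],
                          by = list(plot_id = norm$plot_id), FUN = mean)
  nag <- nag[match(plots$plot_id, nag$plot_id), , drop = FALSE]
  if (anyNA(nag$mat)) stop("missing normal-period climate for some plots")
  cf0 <- climate_modifier(nag$mat, nag$precip, params, nag$t_min, nag$t_max,
                          use_sinusoid = use_sinusoid)
  if (any(cf0 <= 0))
    stop("zero climate factor in the spin-up normal; no finite steady state")

  # scheme climate factors per plot-year
  agg <- aggregate_climate(plots, climate, config$spatial, config$temporal,
                           years = years)
  cf <- matrix(0, n, ny, dimnames = list(plots$plot_id, years))
  fvals <- climate_modifier(agg$mat, agg$precip, params, agg$t_min,
                            agg$t_max, use_sinusoid = use_sinusoid)
  cf[cbind(match(agg$plot_id, plots$plot_id), match(agg$year, years))] <- fvals

  props <- lapply(sz, function(d)
    pool_propagator(params, size_modifier(d, params)))

  # initial pools: analytic steady state under the normal climate
  states <- vector("list", nd)
  stocks <- matrix(0, n, ny, dimnames = list(plots$plot_id, years))
  init_total <- numeric(n)
  for (d in seq_len(nd)) {
    b <- litter$spin_input[, d, , drop = TRUE]
    if (is.null(dim(b))) b <- matrix(b, nrow = n)
    x <- -(b %*% t(props[[d]]$base_inv)) / cf0
    states[[d]] <- x
    init_total <- init_total + rowSums(x)
  }
  for (t in seq_len(ny)) {
    cft <- cf[, t]
    for (d in seq_len(nd)) {
      bd <- litter$input[, t, d, , drop = TRUE]
      if (is.null(dim(bd))) bd <- matrix(bd, nrow = n)
      states[[d]] <- propagate_pools(states[[d]], bd, props[[d]], cft)
      stocks[, t] <- stocks[, t] + rowSums(states[[d]])
    }
  }
  pools <- array(unlist(states), c(n, 5, nd),
                 dimnames = list(plots$plot_id, POOLS, paste0("d", sz)))
  pools <- aperm(pools, c(1, 3, 2))
  structure(list(stocks = stocks, initial = init_total, pools = pools,
                 config = config, years = years,
                 plots = plots[c("plot_id", "district", "region",
                                 "rep_area_ha", "species", "age")]),
            class = "awenh_sim")
}

#' Scale per-plot stock changes to a national total
#'
#' Each plot stands for its representation area; the national change is the
#' sum over plots of (change per m^2 x represented area), reported in
#' Gg C (1 Gg = 1e6 kg).
#'
#' @param changes Per-plot soil carbon changes, kg C m^-2 (per year or per
#'   period — the result carries the same time basis).
#' @param rep_area_ha Representation areas, ha (> 0), recycled if scalar.
#' @return National change, Gg C.
#' @export
national_change <- function(changes, rep_area_ha) {
  if (any(rep_area_ha <= 0)) stop("representation areas must be > 0")
  if (length(rep_area_ha) != 1L && length(rep_area_ha) != length(changes))
    stop("unit mismatch: one representation area per plot change required")
  sum(changes * rep_area_ha * 1e4) / 1e6   # ha -> m^2, kg -> Gg
}

#' Annual national stock-change series of a simulation
#'
#' @param sim An `awenh_sim`.
#' @return Named numeric vector: national soil carbon change per year
#'   (Gg C yr^-1), for every simulated year (the first year's change is
#'   relative to the steady-state initial stock).
#' @export
national_series <- function(sim) {
  stopifnot(inherits(sim, "awenh_sim"))
  prev <- cbind(sim$initial, sim$stocks[, -ncol(sim$stocks), drop = FALSE])
  ann <- sim$stocks - prev
  out <- apply(ann, 2, national_change, rep_area_ha = sim$plots$rep_area_ha)
  names(out) <- colnames(sim$stocks)
  out
}

#' Mean stock and cumulative change summaries
#'
#' `stock_mean()` is the landscape mean of per-plot mean stocks over a
#' reporting window (default 2008-2012); `cumulative_national_change()`
#' sums the annual national series over a window (default 2000-2012).
#'
#' @param sim An `awenh_sim`.
#' @param window Calendar years of the reporting window.
#' @return A single number (kg C m^-2, or Gg C).
#' @export
stock_mean <- function(sim, window = 2008:2012) {
  cols <- intersect(as.character(window), colnames(sim$stocks))
  if (!length(cols)) stop("reporting window outside the simulated years")
  mean(rowMeans(sim$stocks[, cols, drop = FALSE]))
}

#' @rdname stock_mean
#' @export
cumulative_national_change <- function(sim, window = 2000:2012) {
  ser <- national_series(sim)
  keep <- intersect(as.character(window), names(ser))
  if (!length(keep)) stop("reporting window outside the simulated years")
  sum(ser[keep])
}

#' Per-plot 5-year stock changes
#'
#' Stock differences across each plot's inventory-cycle boundaries within a
#' window, kg C m^-2 per 5 years.
#'
#' @param sim An `awenh_sim`.
#' @param window Calendar years (default 2000:2012).
#' @return A `data.frame`: `plot_id`, `year` (end of the 5-year period),
#'   `change`.
#' @export
plot_changes <- function(sim, window = 2000:2012) {
  yrs <- as.integer(colnames(sim$stocks))
  out <- list()
  for (i in seq_len(nrow(sim$stocks))) {
    ends <- yrs[yrs %in% window & (yrs - 5L) %in% yrs]
    ch <- sim$stocks[i, as.character(ends)] -
      sim$stocks[i, as.character(ends - 5L)]
    out[[i]] <- data.frame(plot_id = sim$plots$plot_id[i], year = ends,
                           change = as.numeric(ch))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare completed simulations across aggregation levels
#'
#' Produces a tidy long-format comparison table: one row per scope x
#' period x simulation, covering the country mean stock over the stock
#' window, district mean stocks, district mean 5-year changes over the
#' change window and the national annual change series.
#'
#' @param sims A named list of `awenh_sim` objects (>= 1).
#' @param stock_window,change_window Reporting windows (defaults 2008-2012
#'   and 2000-2012).
#' @return A `data.frame`: `simulation`, `scope`, `unit` (district id,
#'   `"country"`, or year), `period`, `value`, `units`.
#' @export
report <- function(sims, stock_window = 2008:2012,
                   change_window = 2000:2012) {
  if (inherits(sims, "awenh_sim")) sims <- list(sims)
  if (is.null(names(sims)) || any(!nzchar(names(sims))))
    names(sims) <- vapply(sims, function(s) s$config$name, "")
  rows <- list()
  per <- function(w) paste0(min(w), "-", max(w))
  for (nm in names(sims)) {
    s <- sims[[nm]]
    rows[[length(rows) + 1L]] <- data.frame(
      simulation = nm, scope = "country", unit = "country",
      period = per(stock_window), value = stock_mean(s, stock_window),
      units = "kg C m-2")
    pm <- rowMeans(s$stocks[, intersect(as.character(stock_window),
                                        colnames(s$stocks)), drop = FALSE])
    dm <- tapply(pm, s$plots$district, mean)
    rows[[length(rows) + 1L]] <- data.frame(
      simulation = nm, scope = "district", unit = names(dm),
      period = per(stock_window), value = as.numeric(dm),
      units = "kg C m-2")
    pc <- plot_changes(s, change_window)
    pc$district <- s$plots$district[match(pc$plot_id, s$plots$plot_id)]
    dc <- tapply(pc$change, pc$district, mean)
    rows[[length(rows) + 1L]] <- data.frame(
      simulation = nm, scope = "district_change", unit = names(dc),
      period = per(change_window), value = as.numeric(dc),
      units = "kg C m-2 per 5 yr")
    ns <- national_series(s)
    rows[[length(rows) + 1L]] <- data.frame(
      simulation = nm, scope = "national_change", unit = names(ns),
      period = names(ns), value = as.numeric(ns), units = "Gg C yr-1")
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
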