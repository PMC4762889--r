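# All generators take an explicit seed and restore the caller's RNG state,
# so landscape, climate and biomass streams are independently reproducible.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic inventory landscape
#'
#' Builds a plot network emulating a national forest inventory on a regular
#' grid: plots carry district and region membership, a representation area
#' (default 900 ha per plot), a dominant species, stand age, site
#' productivity class, organic-layer thickness (some plots at or above the
#' 0.4 m threshold, so the upland filter has work to do), a first inventory
#' year within the establishment window and the back-cast rule class of the
#' historical-litter rules.  Three climatic regions are represented: a warm
#' and wet south-western coastal region, a colder and drier south-eastern
#' region, and a cold northern region.
#'
#' @param n_plots Number of plots (>= `n_districts`).
#' @param n_districts Number of administrative districts (default 19),
#'   assigned round-robin so plot counts per district are balanced.
#' @param region_map Character vector of length `n_districts` mapping each
#'   district to `"southeast"`, `"southwest"` or `"north"`.  Default splits
#'   districts 42/37/21 percent in that order.
#' @param rule_mix Named probabilities of the back-cast rule classes
#'   (default 0.76 mature, 0.03 young unproductive, 0.19 young productive,
#'   0.02 land-use change); northern low-productivity plots are overridden
#'   to the `"northern_constant"` rule.
#' @param mean_age,sd_age Stand-age distribution (gamma-shaped), years.
#' @param rep_area_ha Representation area per plot, ha.
#' @param seed Integer seed; the landscape is fully reproducible from it.
#' @return A validated plot `data.frame` (see [validate_plots()]).
#' @export
generate_landscape <- function(n_plots, n_districts = 19, region_map = NULL,
                               rule_mix = c(mature = 0.76,
                                            young_unproductive = 0.03,
                                            young_productive = 0.19,
                                            land_use_change = 0.02),
                               mean_age = 70, sd_age = 35,
                               rep_area_ha = 900, seed = 1) {
  if (n_plots < n_districts) stop("n_plots must be >= n_districts")
  if (is.null(region_map)) {
    n_se <- max(1L, round(0.42 * n_districts))
    n_sw <- max(1L, round(0.37 * n_districts))
    n_n <- max(1L, n_districts - n_se - n_sw)
    n_se <- n_districts - n_sw - n_n
    region_map <- rep(c("southeast", "southwest", "north"),
                      c(n_se, n_sw, n_n))
  }
  if (length(region_map) != n_districts)
    stop("region_map must have one entry per district")
  rule_mix <- rule_mix / sum(rule_mix)

  with_seed(seed, {
    district <- rep_len(seq_len(n_districts), n_plots)
    region <- region_map[district]
    species <- sample(c("spruce", "pine", "deciduous"), n_plots,
                      replace = TRUE, prob = c(0.40, 0.35, 0.25))
    site_class <- sample(c("low", "medium", "high"), n_plots,
                         replace = TRUE, prob = c(0.25, 0.50, 0.25))
    shape <- (mean_age / sd_age)^2
    age <- pmax(5, round(stats::rgamma(n_plots, shape = shape,
                                       rate = shape / mean_age)))
    rule <- sample(names(rule_mix), n_plots, replace = TRUE, prob = rule_mix)
    # keep age consistent with the rule class
    young <- rule != "mature"
    age[!young] <- pmax(age[!young], 35)
    age[young] <- pmin(age[young], 34)
    rule[region == "north" & site_class == "low"] <- "northern_constant"
    plots <- data.frame(
      plot_id = seq_len(n_plots),
      district = district,
      region = region,
      rep_area_ha = rep_area_ha,
      species = species,
      age = age,
      site_class = site_class,
      org_layer_m = round(stats::runif(n_plots, 0, 0.47), 3),
      first_year = sample(1986:1993, n_plots, replace = TRUE),
      rule_class = rule,
      stringsAsFactors = FALSE
    )
    validate_plots(plots)
    plots
  })
}

#' Default regional climate baselines
#'
#' Plausible long-term means for the three synthetic regions (configuration
#' defaults, not values from any data set): a warm-wet coastal southwest,
#' a colder and drier southeast, and a cold north.  `amp` is the seasonal
#' half-amplitude used to set the lowest/highest monthly temperatures.
#' @return A named list of `c(mat, precip, amp)` per region (degC, mm, degC).
#' @export
climate_baselines <- function() {
  list(southeast = c(mat = 3, precip = 700, amp = 10),
       southwest = c(mat = 6, precip = 2000, amp = 7),
       north = c(mat = 0, precip = 600, amp = 12))
}

#' Generate synthetic plot climate series
#'
#' Per plot-year climate records over `years`: a regional baseline, fixed
#' district and plot offsets (the spatial gradient), a linear post-1990
#' warming and wetting trend, and independent interannual noise.  With zero
#' noise and zero trends every plot's series is constant; the 1991-2008 mean
#' then recovers its baseline plus the trend midpoint exactly.
#'
#' @param plots Plot table from [generate_landscape()].
#' @param years Calendar years to cover (default 1956:2012).
#' @param baselines Regional baselines, as [climate_baselines()].
#' @param temp_trend,precip_trend Linear trends applied after `trend_start`
#'   (degC yr^-1 and mm yr^-1; defaults 0.04 and 3).
#' @param trend_start First year affected by the trend (default 1991).
#' @param temp_noise_sd Interannual temperature noise, degC (default 0.6).
#' @param precip_noise_cv Interannual multiplicative precipitation noise,
#'   coefficient of variation (default 0.08).
#' @param district_temp_sd,plot_temp_sd Fixed spatial temperature offsets,
#'   degC.
#' @param district_precip_cv,plot_precip_cv Fixed relative spatial
#'   precipitation offsets.
#' @param seed Integer seed.
#' @return A climate `data.frame`: `plot_id`, `year`, `mat`, `t_min`,
#'   `t_max`, `precip`.
#' @export
generate_climate <- function(plots, years = 1956:2012,
                             baselines = climate_baselines(),
                             temp_trend = 0.04, precip_trend = 3,
                             trend_start = 1991,
                             temp_noise_sd = 0.6, precip_noise_cv = 0.08,
                             district_temp_sd = 0.5, plot_temp_sd = 0.4,
                             district_precip_cv = 0.10,
                             plot_precip_cv = 0.06, seed = 1) {
  validate_plots(plots)
  miss <- setdiff(unique(plots$region), names(baselines))
  if (length(miss)) stop("no baseline for region(s): ",
                         paste(miss, collapse = ", "))
  n <- nrow(plots)
  with_seed(seed, {
    dists <- sort(unique(plots$district))
    d_t <- stats::rnorm(length(dists), 0, district_temp_sd)
    d_p <- stats::rnorm(length(dists), 0, district_precip_cv)
    p_t <- stats::rnorm(n, 0, plot_temp_sd)
    p_p <- stats::rnorm(n, 0, plot_precip_cv)
    base <- do.call(rbind, baselines)[plots$region, , drop = FALSE]
    mat0 <- base[, "mat"] + d_t[match(plots$district, dists)] + p_t
    pre0 <- base[, "precip"] *
      (1 + d_p[match(plots$district, dists)]) * (1 + p_p)
    amp <- base[, "amp"]

    ny <- length(years)
    trend_yrs <- pmax(0, years - (trend_start - 1))
    mat <- outer(mat0, rep(1, ny)) + outer(rep(1, n), trend_yrs * temp_trend)
    pre <- outer(pre0, rep(1, ny)) + outer(rep(1, n), trend_yrs * precip_trend)
    if (temp_noise_sd > 0)
      mat <- mat + matrix(stats::rnorm(n * ny, 0, temp_noise_sd), n, ny)
    if (precip_noise_cv > 0)
      pre <- pre * matrix(pmax(0, stats::rnorm(n * ny, 1, precip_noise_cv)),
                          n, ny)
    pre <- pmax(pre, 0)
    out <- data.frame(
      plot_id = rep(plots$plot_id, times = ny),
      year = rep(years, each = n),
      mat = as.vector(mat),
      t_min = as.vector(mat) - rep(amp, times = ny),
      t_max = as.vector(mat) + rep(amp, times = ny),
      precip = as.vector(pre)
    )
    out <- out[order(out$plot_id, out$year), , drop = FALSE]
    rownames(out) <- NULL
    validate_climate(out)
    out
  })
}

# logistic age-biomass curve; asymptote by species x site productivity
biomass_asymptote <- function(species, site_class) {
  k <- list(spruce = c(low = 4.0, medium = 6.5, high = 9.0),
            pine = c(low = 3.5, medium = 5.5, high = 7.5),
            deciduous = c(low = 2.5, medium = 4.0, high = 5.5))
  mapply(function(s, sc) k[[s]][[sc]], species, site_class, USE.NAMES = FALSE)
}

biomass_age_curve <- function(age, asymptote, age50 = 50, slope = 15) {
  asymptote / (1 + exp(-(age - age50) / slope))
}

# fixed component shares of total tree biomass; fine roots tied to foliage
component_shares <- function(species) {
  fol <- c(spruce = 0.13, pine = 0.05, deciduous = 0.04)[[species]]
  raw <- c(foliage = fol, fine_roots = 0.3 * fol, branches = 0.15,
           stem = 0.48, stump = 0.06, coarse_roots = 0.18)
  raw / sum(raw)
}

#' Generate per-cycle biomass components
#'
#' Produces, for every plot and every 5-year inventory year, the biomass
#' components the litter bookkeeping consumes: tree components following a
#' logistic age-biomass curve (asymptote by species and site productivity,
#' a fixed plot-level lognormal multiplier for between-stand variability,
#' fine roots tied to foliage by the 0.3 ratio rule), ground-vegetation
#' above-ground biomass declining with canopy age, an annual natural
#' mortality fraction, and occasional clear-cut harvests once a stand
#' passes its recommended harvest age (the stand then restarts near age
#' zero).  Without harvests the biomass trajectory of a plot is
#' non-decreasing in time.
#'
#' @param plots Plot table.
#' @param last_year Last inventory year to generate (default 2012).
#' @param mortality_frac Annual fraction of standing biomass dying
#'   (default 0.005); a free parameter of the generator.
#' @param harvest_prob Probability per 5-year cycle that a stand past its
#'   recommended harvest age is clear-cut (default 0.3).
#' @param plot_cv Lognormal coefficient of variation of the fixed plot-level
#'   biomass multiplier (default 0.2).
#' @param rules Back-cast rules (for the recommended harvest ages).
#' @param seed Integer seed.
#' @return A `data.frame` with one row per plot x inventory year: biomass
#'   components (kg C m^-2), `gv_*` above-ground ground-vegetation classes,
#'   `mortality_frac` (annual), `harvest_frac` (fraction of the stand
#'   harvested during the following cycle) and `age` (stand age that year).
#' @export
generate_biomass <- function(plots, last_year = 2012, mortality_frac = 0.005,
                             harvest_prob = 0.3, plot_cv = 0.2,
                             rules = backcast_rules(), seed = 1) {
  validate_plots(plots)
  cols <- c("plot_id", "year", "foliage", "fine_roots", "branches", "stem",
            "stump", "coarse_roots", "gv_moss", "gv_lichen", "gv_herbs",
            "gv_shrubs", "mortality_frac", "harvest_frac", "age")
  with_seed(seed, {
    mult <- stats::rlnorm(nrow(plots), -0.5 * log(1 + plot_cv^2),
                          sqrt(log(1 + plot_cv^2)))
    rows <- vector("list", nrow(plots))
    for (i in seq_len(nrow(plots))) {
      p <- plots[i, ]
      yrs <- inventory_years(p$first_year, last_year)
      kk <- biomass_asymptote(p$species, p$site_class) * mult[i]
      h_age <- rules$harvest_age[[p$site_class]]
      shares <- component_shares(p$species)
      age <- p$age
      rec <- matrix(0, length(yrs), length(cols),
                    dimnames = list(NULL, cols))
      for (j in seq_along(yrs)) {
        total <- biomass_age_curve(age, kk)
        gv_total <- gv_above_total(p$species, age)
        harv <- 0
        if (age >= h_age && stats::runif(1) < harvest_prob) harv <- 1
        rec[j, ] <- c(p$plot_id, yrs[j], shares * total,
                      0.50 * gv_total, 0.05 * gv_total, 0.20 * gv_total,
                      0.25 * gv_total, mortality_frac, harv, age)
        age <- if (harv > 0) 2 else age + 5
      }
      rows[[i]] <- rec
    }
    out <- as.data.frame(do.call(rbind, rows))
    rownames(out) <- NULL
    out
  })
}

# ground vegetation declines as the canopy closes with stand age
gv_above_total <- function(species, age) {
  base <- c(spruce = 0.15, pine = 0.25, deciduous = 0.20)[[species]]
  base * (0.5 + 1 / (1 + age / 30))
}

#' Validate a biomass table
#' @param biomass A biomass `data.frame` from [generate_biomass()] or the
#'   same schema.
#' @return The table, invisibly.
#' @export
validate_biomass <- function(biomass) {
  need <- c("plot_id", "year", "foliage", "fine_roots", "branches", "stem",
            "stump", "coarse_roots", "gv_moss", "gv_lichen", "gv_herbs",
            "gv_shrubs", "mortality_frac", "harvest_frac")
  miss <- setdiff(need, names(biomass))
  if (length(miss)) stop("biomass table missing column(s): ",
                         paste(miss, collapse = ", "))
  num <- setdiff(need, c("plot_id", "year"))
  if (any(as.matrix(biomass[num]) < 0)) stop("negative biomass entries")
  if (any(biomass$mortality_frac > 1) || any(biomass$harvest_frac > 1))
    stop("mortality/harvest fractions must lie in [0, 1]")
  invisible(biomass)
}
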