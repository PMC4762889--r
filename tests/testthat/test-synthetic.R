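test_that("generators are fully reproducible from their seeds", {
  a <- generate_landscape(50, seed = 9)
  b <- generate_landscape(50, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, generate_landscape(50, seed = 10)))
  cl1 <- generate_climate(a, seed = 3)
  expect_identical(cl1, generate_climate(a, seed = 3))
  bm1 <- generate_biomass(a, seed = 4)
  expect_identical(bm1, generate_biomass(a, seed = 4))
  # seeding is local: the global RNG stream is untouched
  set.seed(123); before <- runif(5)
  set.seed(123); invisible(generate_landscape(20, seed = 1))
  expect_identical(runif(5), before)
})

test_that("landscape structure matches its configuration", {
  pl <- generate_landscape(19, n_districts = 19, seed = 2)
  expect_equal(sort(pl$district), 1:19)  # one plot per district
  pl <- generate_landscape(400, seed = 2)
  expect_setequal(unique(pl$region), c("southeast", "southwest", "north"))
  expect_true(all(pl$rep_area_ha == 900))
  expect_true(any(pl$org_layer_m >= 0.4) && any(pl$org_layer_m < 0.4))
  # rule classes consistent with stand age
  expect_true(all(pl$age[pl$rule_class == "mature"] >= 35))
  expect_true(all(pl$age[pl$rule_class %in%
                           c("young_unproductive", "young_productive",
                             "land_use_change")] <= 34))
  expect_true(all(pl$first_year %in% 1986:1993))
  expect_silent(validate_plots(pl))
})

test_that("generated age distribution matches the configured mean", {
  # independent Monte-Carlo oracle replicating the draw + rule truncation
  n <- 4000; mean_age <- 70; sd_age <- 35
  pl <- generate_landscape(n, mean_age = mean_age, sd_age = sd_age, seed = 13)
  oracle <- local({
    set.seed(999)
    shape <- (mean_age / sd_age)^2
    reps <- replicate(200, {
      age <- pmax(5, round(rgamma(n, shape = shape, rate = shape / mean_age)))
      young <- runif(n) > 0.76
      mean(ifelse(young, pmin(age, 34), pmax(age, 35)))
    })
    c(mean(reps), sd(reps))
  })
  expect_lt(abs(mean(pl$age) - oracle[1]), 3 * oracle[2] + 3 * sd_age / sqrt(n))
})

test_that("climate series carry the configured baselines, trend and noise", {
  pl <- generate_landscape(30, seed = 5)
  # zero noise, zero trend, zero offsets: constant series at the baseline
  cl <- generate_climate(pl, temp_noise_sd = 0, precip_noise_cv = 0,
                         district_temp_sd = 0, plot_temp_sd = 0,
                         district_precip_cv = 0, plot_precip_cv = 0,
                         temp_trend = 0, precip_trend = 0, seed = 6)
  base <- climate_baselines()
  for (i in c(1, 10)) {
    d <- cl[cl$plot_id == pl$plot_id[i], ]
    expect_equal(length(unique(d$mat)), 1L)
    expect_equal(d$mat[1], base[[pl$region[i]]][["mat"]])
    expect_equal(d$precip[1], base[[pl$region[i]]][["precip"]])
    expect_true(all(d$t_min <= d$mat & d$mat <= d$t_max))
  }
  # a 0.05 degC/yr trend shifts the endpoint by +1.0 degC over 20 years
  cl <- generate_climate(pl, temp_noise_sd = 0, precip_noise_cv = 0,
                         district_temp_sd = 0, plot_temp_sd = 0,
                         district_precip_cv = 0, plot_precip_cv = 0,
                         temp_trend = 0.05, precip_trend = 0, seed = 6)
  d <- cl[cl$plot_id == pl$plot_id[1], ]
  expect_equal(d$mat[d$year == 2010] - d$mat[d$year == 1990], 1.0,
               tolerance = 1e-12)
  # the 1991-2008 mean matches the closed-form mean of the linear trend
  expect_equal(mean(d$mat[d$year %in% 1991:2008]),
               base[[pl$region[1]]][["mat"]] + 0.05 * mean(1:18),
               tolerance = 1e-12)
})

test_that("biomass trajectories are age-coherent and feed the expected litter ordering", {
  pl <- generate_landscape(40, seed = 8)
  pl$age <- 1  # newly established stands
  bm <- generate_biomass(pl, harvest_prob = 0, seed = 9)
  first <- bm[bm$year == bm$year[1] & bm$plot_id == bm$plot_id[1], ]
  expect_lt(first$stem, 0.5)  # near-zero biomass at age ~0
  # without harvest the per-plot trajectory is non-decreasing
  for (id in pl$plot_id[1:5]) {
    tr <- bm[bm$plot_id == id, ]
    expect_true(all(diff(tr[order(tr$year), "stem"]) >= 0))
  }
  # deterministic curve evaluation: spruce sheds more foliage litter than
  # pine at age 80 on the same site, and a spruce stand out-produces a
  # deciduous one in total living litter
  mk <- function(sp) {
    pl1 <- data.frame(plot_id = 1L, district = 1L, region = "southeast",
                      rep_area_ha = 900, species = sp, age = 80,
                      site_class = "medium", org_layer_m = 0.1,
                      first_year = 1990, rule_class = "mature",
                      stringsAsFactors = FALSE)
    b <- generate_biomass(pl1, harvest_prob = 0, plot_cv = 0, seed = 1)
    b[b$year == 1990, ]
  }
  tt <- default_turnover()
  rate <- function(s) tt$rate[tt$species == s & tt$component == "foliage"]
  expect_gt(mk("spruce")$foliage * rate("spruce"),
            mk("pine")$foliage * rate("pine"))
  tot <- function(sp) {
    b <- mk(sp)
    litter_total(litter_from_living(as.list(b), sp))
  }
  expect_gt(tot("spruce"), tot("deciduous"))
  expect_gt(tot("spruce"), tot("pine"))
})

test_that("generated data passes the pipeline schema validators", {
  w <- tiny_world(25, seed = 77)
  expect_silent(validate_plots(w$plots))
  expect_silent(validate_biomass(w$biomass))
  expect_silent(awenh:::validate_climate(w$climate))
  # and survives a delimited-text round trip unchanged
  f <- tempfile(fileext = ".tsv")
  write.table(w$plots, f, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- read.delim(f, stringsAsFactors = FALSE)
  expect_equal(back, w$plots, tolerance = 1e-12, ignore_attr = TRUE)
})
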