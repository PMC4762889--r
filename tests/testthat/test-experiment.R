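test_that("simulation configs map the factorial design", {
  s1 <- simulation_config("I")
  expect_equal(c(s1$spatial, s1$temporal), c("plot", "longterm"))
  s5 <- simulation_config("V")
  expect_equal(c(s5$spatial, s5$temporal), c("plot", "annual"))
  ext <- simulation_config(spatial = "country", temporal = "annual")
  expect_match(ext$name, "extension")
  expect_equal(simulation_config(spatial = "district",
                                 temporal = "longterm")$name, "II")
})

test_that("upland filter keeps strictly thin organic layers", {
  plots <- data.frame(plot_id = 1:4, org_layer_m = c(0.39, 0.40, 0.05, 0.55))
  kept <- filter_upland(plots)
  expect_equal(kept$plot_id, c(1L, 3L))
  # brute-force count oracle on a generated set
  pl <- generate_landscape(300, seed = 17)
  expect_equal(nrow(filter_upland(pl)), sum(pl$org_layer_m < 0.4))
})

test_that("national change is exact unit arithmetic over representation areas", {
  # 0.001 kg C m-2 yr-1 on 900 ha = 9 Mg = 0.009 Gg
  expect_equal(national_change(0.001, 900), 0.009)
  expect_equal(national_change(rep(0, 10), rep(900, 10)), 0)
  set.seed(2)
  ch <- rnorm(40, 0, 0.01); ar <- runif(40, 100, 2000)
  brute <- sum(vapply(seq_along(ch),
                      function(i) ch[i] * ar[i] * 1e4 / 1e6, numeric(1)))
  expect_equal(national_change(ch, ar), brute, tolerance = 1e-12)
  expect_error(national_change(ch, ar[1:3]), "unit mismatch")
  expect_error(national_change(ch, -1), "> 0")
})

test_that("aggregation is a no-op when plots share identical climate", {
  pl <- generate_landscape(12, n_districts = 1,
                           region_map = "southeast", seed = 4)
  pl <- filter_upland(pl)
  cl <- generate_climate(pl, temp_noise_sd = 0, precip_noise_cv = 0,
                         district_temp_sd = 0, plot_temp_sd = 0,
                         district_precip_cv = 0, plot_precip_cv = 0,
                         seed = 5)
  bm <- generate_biomass(pl, seed = 6)
  lt <- build_litter_series(pl, bm)
  s1 <- run_simulation("I", pl, cl, lt)
  s2 <- run_simulation("II", pl, cl, lt)
  s3 <- run_simulation("III", pl, cl, lt)
  expect_equal(s1$stocks, s2$stocks, tolerance = 1e-12)
  expect_equal(s1$stocks, s3$stocks, tolerance = 1e-12)
  # with no trend and no interannual noise the temporal schemes coincide too
  cl0 <- generate_climate(pl, temp_noise_sd = 0, precip_noise_cv = 0,
                          district_temp_sd = 0, plot_temp_sd = 0,
                          district_precip_cv = 0, plot_precip_cv = 0,
                          temp_trend = 0, precip_trend = 0, seed = 5)
  lt0 <- build_litter_series(pl, bm)
  sI <- run_simulation("I", pl, cl0, lt0)
  sV <- run_simulation("V", pl, cl0, lt0)
  expect_equal(sI$stocks, sV$stocks, tolerance = 1e-10)
})

test_that("zero litter input produces monotonically declining stocks", {
  w <- tiny_world(10, seed = 41)
  lt <- build_litter_series(w$plots, w$biomass)
  lt$input[] <- 0
  s <- run_simulation("I", w$plots, w$climate, lt)
  expect_true(all(s$stocks > 0))
  expect_true(all(diff(t(s$stocks)) < 0))
})

test_that("runs are deterministic and stocks/changes are mutually consistent", {
  w <- tiny_world(15, seed = 51)
  lt <- build_litter_series(w$plots, w$biomass)
  a <- run_simulation("IV", w$plots, w$climate, lt)
  b <- run_simulation("IV", w$plots, w$climate, lt)
  expect_identical(a$stocks, b$stocks)
  # 5-year change equals the difference of reported stocks per plot
  pc <- plot_changes(a, window = 2000:2012)
  for (k in sample(nrow(pc), 20)) {
    i <- match(pc$plot_id[k], a$plots$plot_id)
    expect_equal(pc$change[k],
                 a$stocks[i, as.character(pc$year[k])] -
                   a$stocks[i, as.character(pc$year[k] - 5)],
                 ignore_attr = TRUE)
  }
  # the national series sums plot-by-plot annual changes exactly
  ns <- national_series(a)
  y <- "2005"
  prev <- a$stocks[, "2004"]
  brute <- sum((a$stocks[, y] - prev) * a$plots$rep_area_ha * 1e4) / 1e6
  expect_equal(ns[[y]], brute, tolerance = 1e-12)
})

test_that("aggregation hypotheses hold directionally on a trending landscape", {
  w <- tiny_world(120, seed = 61)
  lt <- build_litter_series(w$plots, w$biomass)
  sI <- run_simulation("I", w$plots, w$climate, lt)
  sIII <- run_simulation("III", w$plots, w$climate, lt)
  sV <- run_simulation("V", w$plots, w$climate, lt)
  # H1: country-scale climate input lowers the mean national stock
  expect_lt(stock_mean(sIII), stock_mean(sI))
  # H2: long-term-mean climate yields the higher cumulative change under a
  # post-1990 warming trend
  expect_lt(cumulative_national_change(sV), cumulative_national_change(sI))
})

test_that("report builds tidy comparison tables across simulations", {
  w <- tiny_world(20, seed = 71)
  lt <- build_litter_series(w$plots, w$biomass)
  sI <- run_simulation("I", w$plots, w$climate, lt)
  sIII <- run_simulation("III", w$plots, w$climate, lt)
  one <- report(sI)
  expect_true(all(one$simulation == "I"))
  both <- report(list(I = sI, III = sIII))
  expect_setequal(unique(both$simulation), c("I", "III"))
  cs <- both[both$scope == "country", ]
  expect_equal(nrow(cs), 2L)
  delta <- diff(cs$value)
  expect_equal(abs(delta), abs(stock_mean(sI) - stock_mean(sIII)),
               tolerance = 1e-12)
  dd <- both[both$scope == "district", ]
  expect_equal(sort(unique(dd$unit)), sort(unique(as.character(w$plots$district))))
  expect_s3_class(summary(sI), "summary.awenh_sim")
})
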