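# A lightweight hand-built scenario_result for exact metric arithmetic.
fake_result <- function(series, yu = 2, yf = 2, guild = "g1", day = "90") {
  nyears <- yu + yf
  biomass <- array(series, c(nyears, 1, 1),
                   dimnames = list(NULL, day, guild))
  structure(list(biomass = biomass,
                 catch = matrix(series, nyears, 1,
                                dimnames = list(NULL, "f1")),
                 production = matrix(0, nyears, 1),
                 years_unfished = yu, years_fished = yf,
                 record_days = as.numeric(day)),
            class = "scenario_result")
}

test_that("percent change computes the elementary cases exactly", {
  base <- fake_result(c(100, 100, 100, 100))
  up <- fake_result(c(101, 101, 101, 101))
  expect_equal(percent_change(up, base, "g1", "unfished"), 1)
  expect_equal(percent_change(up, base, "g1", "fished"), 1)
  expect_equal(percent_change(base, base, "g1", "unfished"), 0)
  expect_warning(
    pc <- percent_change(up, fake_result(c(0, 0, 0, 0)), "g1", "unfished"),
    "zero")
  expect_true(is.na(pc))
})

test_that("percent change is antisymmetric up to the baseline scale", {
  for (s in 1:20) {
    set.seed(s)
    a <- fake_result(stats::runif(4, 10, 100))
    b <- fake_result(stats::runif(4, 10, 100))
    ya <- percent_change(a, b, "g1", "unfished", per_year = TRUE)
    yb <- percent_change(b, a, "g1", "unfished", per_year = TRUE)
    av <- a$biomass[1:2, 1, 1]; bv <- b$biomass[1:2, 1, 1]
    expect_equal(ya, -yb * av / bv, tolerance = 1e-12)
  }
})

test_that("percent change matches the closed-form logistic comparison", {
  # doubling r in a pure logistic producer: end states are known analytically
  K <- 1000; B0 <- 50
  run_for <- function(r) {
    web <- make_toy_web("logistic", K = K, r = r)
    cfg <- scenario_config(web, years_unfished = 1, years_fished = 0,
                           init = c(producer = B0))
    run_scenario(cfg)
  }
  res1 <- run_for(0.05)
  res2 <- run_for(0.10)
  logi <- function(r, t) K / (1 + (K / B0 - 1) * exp(-r * t))
  want <- 100 * (logi(0.10, 90) - logi(0.05, 90)) / logi(0.05, 90)
  got <- percent_change(res2, res1, "producer", "unfished", window = 1)
  expect_equal(got, want, tolerance = 1e-5)
})

test_that("prey aggregates are elementwise sums and validate membership", {
  web <- make_lc_like_web()
  cfg <- scenario_config(web, stocking = preset_stocking("wht200"),
                         years_unfished = 2, years_fished = 0)
  res <- run_scenario(cfg)
  adult <- prey_aggregate(res, "adult_prey")
  manual <- guild_series(res, "daphnia") + guild_series(res, "cyclopoid") +
    guild_series(res, "leptodora")
  expect_equal(adult, manual)
  larval <- prey_aggregate(res, "larval_prey")
  expect_equal(larval,
               guild_series(res, c("rotifer_small", "rotifer_medium",
                                   "rotifer_large", "daphnia", "cyclopoid")))
  # a single-guild aggregate is that guild's series
  expect_equal(prey_aggregate(res, "daphnia"), guild_series(res, "daphnia"))
  expect_error(prey_aggregate(res, c("daphnia", "kraken")), "kraken")
  # aggregates are linear in the state
  expect_equal(prey_aggregate(res, c("daphnia", "cyclopoid")),
               guild_series(res, "daphnia") + guild_series(res, "cyclopoid"))
})

test_that("stability CV uses the population convention and is scale-free", {
  expect_equal(stability_cv(rep(7, 10), window = 10)$cv, 0)
  x <- c(1, 1, 1, 3)
  m <- mean(x)
  want <- sqrt(mean((x - m)^2)) / m
  expect_equal(stability_cv(x, window = 4)$cv, want)
  set.seed(1)
  y <- stats::runif(30, 1, 5)
  expect_equal(stability_cv(y, window = 10)$cv,
               stability_cv(y * 137.5, window = 10)$cv, tolerance = 1e-12)
  # sliding windows are indexed by their start year
  out <- stability_cv(y, window = 10)
  expect_equal(out$window_start, 1:21)
  expect_warning(cv0 <- stability_cv(c(-1, -1, -1, -1), window = 4),
                 "nonpositive")
  expect_true(is.na(cv0$cv))
})

test_that("catch comparison mirrors percent change on the fished period", {
  a <- fake_result(c(5, 5, 10, 20))
  b <- fake_result(c(5, 5, 10, 10))
  out <- catch_comparison(a, b)
  expect_equal(unname(out), mean(c(0, 100)))
  expect_equal(unname(catch_comparison(a, a)), 0)
  none <- fake_result(c(1, 2), yu = 2, yf = 0)
  expect_length(catch_comparison(none, none), 0)
})
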